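#' Per-boundary accession transition profile
#'
#' For each pair of successive windows on a chromosome, counts the
#' accessions whose AHG label differs across the boundary.  Masked cells
#' are skipped: an accession's comparison pairs its successive non-masked
#' windows, and a transition is attributed to the boundary immediately
#' left of the later window.
#'
#' @param x an [introblocker()] fit or label matrix.
#' @param chrom per-window chromosome names (from the fit when given).
#' @return Named list per chromosome of integer vectors, element `b`
#'   giving the transition count at the boundary between windows `b` and
#'   `b + 1` of that chromosome.
#' @export
transition_profile <- function(x, chrom = NULL) {
  lm <- as_label_matrix(x)
  if (is.null(chrom)) chrom <- lm$chrom
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  out <- list()
  for (ch in unique(chrom)) {
    block <- lab[, chrom == ch, drop = FALSE]
    nwc <- ncol(block)
    prof <- integer(max(nwc - 1L, 0L))
    for (i in seq_len(nrow(block))) {
      v <- block[i, ]
      idx <- which(!is.na(v))
      if (length(idx) < 2L) next
      sw <- which(v[idx][-1L] != v[idx][-length(idx)])
      prof[idx[sw + 1L] - 1L] <- prof[idx[sw + 1L] - 1L] + 1L
    }
    out[[ch]] <- prof
  }
  out
}

#' Locate the centromeric AHG block of a chromosome
#'
#' Chromosomes of selfing cereals carry a large recombination-suppressed
#' central zone in which the AHG mosaic is stable across most accessions.
#' The block is located from the boundary transition profile: the profile
#' is smoothed by the median over the flanking `flank` boundaries
#' (`flank / 2` on each side, excluding the boundary itself, truncated at
#' chromosome ends), and the block spans from the first run of `run`
#' consecutive boundaries with smoothed transitions below the threshold
#' to the last such run.  The threshold defaults to 15 accessions, the
#' value appropriate for a cohort of 386; for other cohort sizes pass
#' `n_accessions` and the threshold scales as `frac * n_accessions`.
#' An absent block is a valid result (`NULL`).  Candidate blocks outside
#' the configured span bounds are reported but flagged, mirroring the
#' manual-review step such scans require.
#'
#' @param profile integer vector of per-boundary transition counts for one
#'   chromosome (one element of [transition_profile()]).
#' @param flank smoothing span in boundaries (default 16, 8 per side).
#' @param max_transitions absolute transition threshold (default 15).
#' @param run required consecutive below-threshold boundaries (default 5).
#' @param n_accessions optional cohort size; when given the threshold is
#'   `frac * n_accessions` instead of `max_transitions`.
#' @param frac fractional threshold (default 15/386).
#' @param span_bounds expected block span in windows `c(min, max)` or
#'   `NULL` to skip the flag (default `NULL`; with 5-Mbp windows the wheat
#'   expectation 80-250 Mbp is `c(16, 50)`).
#' @return `NULL`, or a `centahg_block` list: `start_window`,
#'   `end_window` (inclusive window indices), `smoothed` profile,
#'   `threshold`, `span_ok`.
#' @export
locate_centahg <- function(profile, flank = 16, max_transitions = 15,
                           run = 5, n_accessions = NULL, frac = 15 / 386,
                           span_bounds = NULL) {
  nb <- length(profile)
  if (nb < run) return(NULL)
  thr <- if (is.null(n_accessions)) max_transitions else frac * n_accessions
  half <- max(1L, floor(flank / 2))
  sm <- vapply(seq_len(nb), function(i) {
    lo <- max(1L, i - half); hi <- min(nb, i + half)
    idx <- setdiff(lo:hi, i)
    median(profile[idx])
  }, numeric(1))
  low <- sm < thr
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= run)
  if (!length(good)) return(NULL)
  b1 <- starts[good[1]]
  b2 <- ends[good[length(good)]]
  # boundary b sits between windows b and b+1
  blk <- list(start_window = b1, end_window = b2 + 1L, smoothed = sm,
              threshold = thr, span_ok = TRUE)
  if (!is.null(span_bounds)) {
    span <- blk$end_window - blk$start_window + 1L
    blk$span_ok <- span >= span_bounds[1] && span <= span_bounds[2]
  }
  structure(blk, class = "centahg_block")
}

#' @export
print.centahg_block <- function(x, ...) {
  cat(sprintf("centAHG block: windows %d-%d (threshold %.1f transitions%s)\n",
              x$start_window, x$end_window, x$threshold,
              if (x$span_ok) "" else ", span outside expected bounds"))
  invisible(x)
}

#' Type accessions by their centromeric AHG
#'
#' Within the block the AHG of an accession is nearly constant, so the
#' accessions are clustered by the number of block windows at which their
#' labels differ (average linkage) and the tree is cut at `cut` times the
#' maximum merge height.  Types are renumbered by descending frequency.
#'
#' @param x an [introblocker()] fit or label matrix (windows of one
#'   chromosome).
#' @param block a [locate_centahg()] block for that chromosome.
#' @param cut relative cut height in (0, 1), default 0.5.
#' @return A `centahg_typing` list: `type` (named integer per accession),
#'   `freq` (type frequency table), `representative` (first accession of
#'   each type in input order), `block`.
#' @export
type_centahg <- function(x, block, cut = 0.5) {
  if (is.null(block)) stop("no centAHG block located")
  lm <- as_label_matrix(x)
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  win <- block$start_window:block$end_window
  sub <- lab[, win, drop = FALSE]
  n <- nrow(sub)
  d <- matrix(0, n, n, dimnames = list(rownames(sub), rownames(sub)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(sub[i, ]) & !is.na(sub[j, ])
    d[i, j] <- d[j, i] <- sum(sub[i, ok] != sub[j, ok])
  }
  if (n == 1L) {
    raw <- setNames(1L, rownames(sub))
  } else {
    hc <- hclust(as.dist(d), method = "average")
    hmax <- max(hc$height)
    raw <- if (hmax == 0) setNames(rep(1L, n), rownames(sub))
           else cutree(hc, h = cut * hmax)
  }
  freq <- sort(table(raw), decreasing = TRUE)
  remap <- setNames(seq_along(freq), names(freq))
  type <- setNames(as.integer(remap[as.character(raw)]), names(raw))
  rep_acc <- vapply(seq_along(freq), function(t)
    names(type)[type == t][1], character(1))
  structure(list(type = type,
                 freq = table(factor(type, seq_along(freq))),
                 representative = rep_acc, block = block),
            class = "centahg_typing")
}

#' @export
print.centahg_typing <- function(x, ...) {
  cat(sprintf("centAHG typing: %d accessions, %d types\n",
              length(x$type), length(x$freq)))
  print(x$freq)
  invisible(x)
}

#' Trace centromeric AHG types along a group route
#'
#' A type observed in stage `k` of the route is traceable when it is also
#' observed in stage `k - 1`; returns the traceable fraction per stage
#' transition (the stability of the chromosome backbone along
#' domestication).
#'
#' @param typing a [type_centahg()] result (or named type vector).
#' @param groups a [group_assignment()].
#' @param route character vector of group labels, ancestral first
#'   (default `groups$group_order`).
#' @return Data.frame with `from`, `to`, `n_types`, `traceable`,
#'   `fraction`.
#' @export
trace_centahg <- function(typing, groups, route = groups$group_order) {
  type <- if (inherits(typing, "centahg_typing")) typing$type else typing
  types_of <- function(g) {
    ids <- names(groups$groups)[groups$groups == g]
    unique(unname(type[names(type) %in% ids]))
  }
  res <- lapply(seq_len(length(route) - 1L), function(k) {
    prev <- types_of(route[k]); cur <- types_of(route[k + 1L])
    data.frame(from = route[k], to = route[k + 1L], n_types = length(cur),
               traceable = sum(cur %in% prev),
               fraction = if (length(cur)) mean(cur %in% prev) else NA_real_)
  })
  do.call(rbind, res)
}

#' Date centromeric AHG types from within-type distances
#'
#' For every type with at least two members, pools the binwise distances
#' of all member pairs over the block windows, excluding windows where
#' either member's AHG label differs from that member's own majority
#' (centromeric) label — such windows carry recent foreign haplotypes,
#' not the type's ancestral divergence.  The distribution peak is located
#' as the mode of a fixed-width histogram on the log10 scale (a
#' deterministic alternative to kernel density) and converted to years by
#' [date_divergence()].
#'
#' @param wd the cohort's [pairwise_window_distances()].
#' @param block a [locate_centahg()] block.
#' @param typing a [type_centahg()] result.
#' @param x the [introblocker()] fit or label matrix used for the typing
#'   (needed for the per-window mismatch exclusion).
#' @param mu mutation rate per nt per year (default 1.6e-8).
#' @param bin_width histogram bin width in log10 units (default 0.05).
#' @param min_members minimum type size to date (default 2; singletons are
#'   skipped with a warning).
#' @return Data.frame with `type`, `n_members`, `n_distances`,
#'   `peak_distance` (variants/bp), `age_years`, `age_reported`
#'   (nearest hundred).
#' @export
date_centahg_types <- function(wd, block, typing, x, mu = 1.6e-8,
                               bin_width = 0.05, min_members = 2) {
  lm <- as_label_matrix(x)
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  win <- block$start_window:block$end_window
  # each accession's centromeric (majority) label within the block
  major <- apply(lab[, win, drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    as.integer(names(sort(table(v), decreasing = TRUE))[1])
  })
  res <- list()
  for (t in seq_along(typing$freq)) {
    members <- names(typing$type)[typing$type == t]
    if (length(members) < min_members) {
      warning("type ", t, " has fewer than ", min_members,
              " members; skipped")
      next
    }
    mi <- match(members, wd$accessions)
    vals <- numeric(0)
    for (a in seq_along(mi)) for (b in seq_along(mi)) {
      if (a >= b) next
      ok <- !is.na(lab[members[a], win]) & !is.na(lab[members[b], win]) &
        lab[members[a], win] == major[members[a]] &
        lab[members[b], win] == major[members[b]]
      if (any(ok))
        vals <- c(vals, wd$D[mi[a], mi[b], win[ok]])
    }
    vals <- vals[vals > 0]
    if (!length(vals)) next
    peak <- histogram_mode(log10(vals), bin_width)
    age <- date_divergence(10^peak, mu)
    res[[length(res) + 1L]] <-
      data.frame(type = t, n_members = length(members),
                 n_distances = length(vals), peak_distance = 10^peak,
                 age_years = age, age_reported = report_years(age))
  }
  do.call(rbind, res)
}

# mode of a fixed-width histogram anchored at the data minimum; returns
# the midpoint of the fullest bin (ties: the lowest bin)
histogram_mode <- function(x, bin_width) {
  b <- floor((x - min(x)) / bin_width)
  tb <- table(b)
  best <- as.integer(names(tb)[which.max(tb)])
  min(x) + (best + 0.5) * bin_width
}
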