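#' Shannon diversity of AHG labels
#'
#' Base-2 entropy of label frequencies, `H = -sum p_i log2 p_i`.  Zero iff
#' a single label is present; bounded above by `log2(number of labels)`.
#'
#' @param label_counts table or named/plain vector of per-label counts.
#' @return Entropy in bits.
#' @export
shannon_index <- function(label_counts) {
  x <- as.numeric(label_counts)
  x <- x[x > 0]
  if (!length(x)) stop("empty counts")
  p <- x / sum(x)
  -sum(p * log2(p))
}

# labels + mask from a fit or a raw matrix
as_label_matrix <- function(x) {
  if (inherits(x, "introblocker"))
    list(labels = x$labels, mask = x$mask, chrom = x$grid$chrom)
  else
    list(labels = x, mask = matrix(MASK_OK, nrow(x), ncol(x)),
         chrom = rep("chr", ncol(x)))
}

group_rows <- function(labels, groups, g) {
  which(rownames(labels) %in% names(groups$groups)[groups$groups == g])
}

#' Staged Shannon-diversity selection scan
#'
#' Computes, per window, the Shannon index of AHG labels within each group
#' of a staged series (default stages WE > DT > LR > CV), the consecutive
#' stage differences, selection flags for each stage transition
#' (`H` drop exceeding the stage threshold) and per-group fixation flags
#' (`H < fixation_max`).  Masked cells are excluded from all counts;
#' windows flagged as CNV-enriched blocks (`ceb`) are excluded from the
#' selection and fixation flags, since their diversity reflects copy
#' number, not haplotype turnover.  A window where some group has no
#' unmasked accession is flagged `nodata`.
#'
#' @param x an [introblocker()] fit or label matrix.
#' @param groups a [group_assignment()] whose `group_order` lists the
#'   stages from wild to elite.
#' @param stage_thresholds minimum `H` drop per consecutive stage pair
#'   (defaults 1.5, 0.6, 0.3 for WE-DT, DT-LR, LR-CV).
#' @param fixation_max fixation bound on `H` (default 0.05).
#' @param ceb optional logical per-window CNV-enriched-block flags from
#'   [ceb_scan()].
#' @return A `selection_table` data.frame: one row per window with
#'   per-group `H_<group>`, per-stage `d_<g1>_<g2>` and `sel_<g1>_<g2>`,
#'   per-group `fix_<group>`, and `nodata`.
#' @export
selection_scan <- function(x, groups, stage_thresholds = c(1.5, 0.6, 0.3),
                           fixation_max = 0.05, ceb = NULL) {
  lm <- as_label_matrix(x)
  gl <- groups$group_order
  if (length(stage_thresholds) != length(gl) - 1L)
    stop("need one stage threshold per consecutive group pair")
  nw <- ncol(lm$labels)
  if (is.null(ceb)) ceb <- rep(FALSE, nw)
  H <- matrix(NA_real_, nw, length(gl), dimnames = list(NULL, gl))
  nodata <- rep(FALSE, nw)
  for (gi in seq_along(gl)) {
    rows <- group_rows(lm$labels, groups, gl[gi])
    for (w in seq_len(nw)) {
      v <- lm$labels[rows, w]
      v <- v[!is.na(v) & lm$mask[rows, w] == MASK_OK]
      if (!length(v)) { nodata[w] <- TRUE; next }
      H[w, gi] <- shannon_index(table(v))
    }
  }
  out <- data.frame(window = window_label_names(x, nw), H,
                    check.names = FALSE)
  names(out)[-1] <- paste0("H_", gl)
  for (s in seq_len(length(gl) - 1L)) {
    d <- H[, s] - H[, s + 1L]
    sel <- !nodata & !ceb & !is.na(d) & d > stage_thresholds[s]
    out[[paste0("d_", gl[s], "_", gl[s + 1L])]] <- d
    out[[paste0("sel_", gl[s], "_", gl[s + 1L])]] <- sel
  }
  for (gi in seq_along(gl))
    out[[paste0("fix_", gl[gi])]] <- !nodata & !ceb & !is.na(H[, gi]) &
      H[, gi] < fixation_max
  out$ceb <- ceb
  out$nodata <- nodata
  class(out) <- c("selection_table", "data.frame")
  out
}

window_label_names <- function(x, nw) {
  if (inherits(x, "introblocker")) window_names(x$grid)
  else if (!is.null(colnames(if (is.list(x)) x$labels else x)))
    colnames(if (is.list(x)) x$labels else x)
  else paste0("w", seq_len(nw))
}

#' CNV-enriched block scan
#'
#' Per window, the frequency of CNV blocks within each staged group and
#' the maximum absolute frequency jump between consecutive stages,
#' `MaxD(CNV) = max(|F1 - F2|, |F2 - F3|, |F3 - F4|)`; note only
#' consecutive stages are compared, so a slow monotone drift across all
#' stages does not qualify.  A window is a CNV-enriched block (CEB) when
#' `MaxD(CNV) > min_delta`.
#'
#' @param cnv logical accession x window CNV mask from [cnv_blocks()].
#' @param groups a [group_assignment()] with the staged `group_order`.
#' @param min_delta CEB threshold on the frequency jump (default 0.4).
#' @return A `ceb_table` data.frame: per-window group frequencies
#'   `F_<group>`, `max_delta`, and logical `ceb`.
#' @export
ceb_scan <- function(cnv, groups, min_delta = 0.4) {
  gl <- groups$group_order
  Fm <- sapply(gl, function(g) {
    rows <- which(rownames(cnv) %in% names(groups$groups)[groups$groups == g])
    colMeans(cnv[rows, , drop = FALSE])
  })
  if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1, dimnames = list(NULL, gl))
  deltas <- abs(Fm[, -1, drop = FALSE] - Fm[, -ncol(Fm), drop = FALSE])
  max_delta <- apply(deltas, 1, max)
  out <- data.frame(window = colnames(cnv) %||% paste0("w", seq_len(nrow(Fm))),
                    Fm, max_delta = max_delta, ceb = max_delta > min_delta,
                    check.names = FALSE)
  names(out)[1 + seq_along(gl)] <- paste0("F_", gl)
  class(out) <- c("ceb_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Donor contribution and coverage
#'
#' Quantifies how much of a recipient panel's mosaic genome is traceable
#' to each donor accession.  Per donor `i`:
#' `contribution_i = sum_j n_ij / (N_windows * N_recipients)`, where
#' `n_ij` counts the windows of recipient `j` whose AHG label also occurs
#' in donor `i` in the same window, and
#' `coverage_i = m_i / N_windows`, where `m_i` counts the windows of donor
#' `i` whose label occurs in any recipient.  The cumulative contribution
#' walks donors in `donor_order` and credits each shared (recipient,
#' window) cell only to the highest-priority donor sharing it, so the
#' running total is non-decreasing and bounded by 1.
#'
#' @param x an [introblocker()] fit or label matrix.
#' @param donors,recipients disjoint character vectors of accession ids.
#' @param donor_order optional order for the cumulative attribution
#'   (default: donors as given).
#' @return A `contribution_report` data.frame with `donor`,
#'   `contribution`, `coverage`, `cumulative`.
#' @export
contribution <- function(x, donors, recipients, donor_order = donors) {
  lm <- as_label_matrix(x)
  if (!length(recipients)) stop("empty recipient set")
  if (length(intersect(donors, recipients)))
    stop("donors and recipients must be disjoint")
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  bad <- setdiff(c(donors, recipients), rownames(lab))
  if (length(bad)) stop("unknown accession(s): ", paste(bad, collapse = ", "))
  nw <- ncol(lab)
  nr <- length(recipients)
  shares <- function(d) {
    # recipients x windows: recipient label present in donor d's cell
    t(sapply(recipients, function(r)
      !is.na(lab[r, ]) & !is.na(lab[d, ]) & lab[r, ] == lab[d, ]))
  }
  share_list <- lapply(donors, shares)
  names(share_list) <- donors
  contrib <- vapply(share_list, function(s) sum(s) / (nw * nr), numeric(1))
  coverage <- vapply(donors, function(d) {
    hit <- vapply(seq_len(nw), function(w) {
      !is.na(lab[d, w]) && any(!is.na(lab[recipients, w]) &
                                 lab[recipients, w] == lab[d, w])
    }, logical(1))
    sum(hit) / nw
  }, numeric(1))
  taken <- matrix(FALSE, nr, nw)
  cum <- numeric(length(donor_order))
  run <- 0
  for (k in seq_along(donor_order)) {
    s <- share_list[[donor_order[k]]] & !taken
    run <- run + sum(s) / (nw * nr)
    taken <- taken | share_list[[donor_order[k]]]
    cum[k] <- run
  }
  out <- data.frame(donor = donors, contribution = contrib,
                    coverage = coverage,
                    cumulative = cum[match(donors, donor_order)],
                    row.names = NULL)
  class(out) <- c("contribution_report", "data.frame")
  out
}

#' Partition pooled AHGs by group presence pattern
#'
#' Pools the distinct (window, label) pairs over all windows — labels are
#' only comparable within a window, so a pooled "AHG" is such a pair —
#' and counts them by their presence/absence pattern across the groups.
#'
#' @param x an [introblocker()] fit or label matrix.
#' @param groups a [group_assignment()].
#' @return Data.frame with `pattern` (`+`-joined group names), `count`,
#'   `fraction`.
#' @export
shared_ahg_partition <- function(x, groups) {
  lm <- as_label_matrix(x)
  if (length(groups$group_order) < 2L) stop("need at least 2 groups")
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  gl <- groups$group_order
  pres <- list()
  for (g in gl) {
    rows <- group_rows(lab, groups, g)
    sub <- lab[rows, , drop = FALSE]
    keys <- unlist(lapply(seq_len(ncol(lab)), function(w) {
      v <- unique(sub[, w]); v <- v[!is.na(v)]
      if (length(v)) paste(w, v, sep = ":") else character(0)
    }))
    pres[[g]] <- keys
  }
  all_keys <- unique(unlist(pres))
  pat <- sapply(gl, function(g) all_keys %in% pres[[g]])
  if (is.null(dim(pat))) pat <- matrix(pat, nrow = 1, dimnames = list(NULL, gl))
  pattern <- apply(pat, 1, function(p) paste(gl[p], collapse = "+"))
  tab <- table(pattern)
  data.frame(pattern = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / length(all_keys),
             row.names = NULL)
}

#' AHG saturation curve
#'
#' For subset sizes 1 to the group size, repeatedly samples accessions
#' without replacement and records the number of distinct AHG labels per
#' window, averaged over windows; reports mean and 5th/95th percentiles
#' over the resamples at each size.  Flat curves indicate the sampled
#' group already saturates the ancestral diversity.
#'
#' @param x an [introblocker()] fit or label matrix.
#' @param group character vector of accession ids (e.g. one group).
#' @param reps resamples per size (default 100).
#' @param seed integer seed.
#' @return Data.frame with `size`, `mean`, `p5`, `p95`.
#' @export
saturation_curve <- function(x, group, reps = 100, seed = 1) {
  lm <- as_label_matrix(x)
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  if (!length(group)) stop("group is empty")
  lab <- lab[group, , drop = FALSE]
  set.seed(seed)
  n <- length(group)
  distinct_per_window <- function(rows) {
    mean(apply(lab[rows, , drop = FALSE], 2, function(v)
      length(unique(v[!is.na(v)]))))
  }
  res <- lapply(seq_len(n), function(size) {
    vals <- vapply(seq_len(reps), function(r)
      distinct_per_window(sample.int(n, size)), numeric(1))
    data.frame(size = size, mean = mean(vals),
               p5 = unname(quantile(vals, 0.05)),
               p95 = unname(quantile(vals, 0.95)))
  })
  do.call(rbind, res)
}

#' AHG-based accession distance matrix
#'
#' Pairwise distance = number of non-masked windows where the two
#' accessions carry different AHG labels (windows where either cell is
#' masked are skipped).  The matrix is the input for neighbor-joining or
#' principal-coordinate analyses done outside this package;
#' `write_phylip_dist` exports it in square PHYLIP format.
#'
#' @param x an [introblocker()] fit or label matrix.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
ahg_distance_matrix <- function(x) {
  lm <- as_label_matrix(x)
  lab <- lm$labels
  lab[lm$mask != MASK_OK] <- NA
  n <- nrow(lab)
  out <- matrix(0L, n, n, dimnames = list(rownames(lab), rownames(lab)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(lab[i, ]) & !is.na(lab[j, ])
    d <- sum(lab[i, ok] != lab[j, ok])
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' @rdname ahg_distance_matrix
#' @param d matrix from `ahg_distance_matrix`.
#' @param path output path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(format(d[i, ], trim = TRUE), collapse = "  ")), con)
  invisible(path)
}
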