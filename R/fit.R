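#' Infer ancestral haplotype groups across a cohort
#'
#' The main fitting function.  Runs the full inference on binwise pairwise
#' distances: optional CNV masking from normalized read depth, per-window
#' average-linkage clustering cut at the ancestry threshold, greedy
#' core-accession selection and adjacent-swap optimization of the
#' accession priority order (per group in semi-supervised mode), label
#' threading, and Bayesian smoothing against the two-component mixture of
#' the log distance distribution.  The result is a classed fit holding the
#' accession x window AHG label matrix — the mosaic ancestry map.
#'
#' @param wd a [pairwise_window_distances()] object, or a
#'   [genotype_matrix()] (then `grid` must be given and distances are
#'   computed first).
#' @param grid a [make_windows()] grid; required when `wd` is a genotype
#'   matrix, ignored otherwise.
#' @param depth optional [window_depth()] matrix for CNV masking (rows
#'   must match the accessions).
#' @param threshold ancestry threshold in variants/bp (default `1e-3`);
#'   see [derive_threshold()] for deriving it from a mixture fit.
#' @param groups optional [group_assignment()]; switches to
#'   semi-supervised mode, where whole groups are ordered by
#'   `groups$group_order` and only within-group order is optimized.
#' @param smooth apply Bayesian smoothing (default TRUE).
#' @param fit optional precomputed 2-component [fit_distance_mixture()];
#'   when absent and smoothing is on, a mixture is fitted to up to
#'   `n_fit_pairs` randomly sampled accession pairs (seeded).
#' @param flank,ratio smoothing parameters, see [bayesian_smooth()].
#' @param coverage Step 2.1 coverage stop, see [select_core_accessions()].
#' @param cnv_low,cnv_high CNV depth bounds, see [cnv_blocks()].
#' @param n_fit_pairs pairs sampled for the internal mixture fit.
#' @param seed seed for the pair sampling (the rest is deterministic).
#' @return An object of class `introblocker`: list with `labels` (integer
#'   accession x window matrix, labels dense and numbered by priority of
#'   their dominating accession), `mask` (codes 0 OK / 1 CNV / 2 no data),
#'   `dominator` (character vector, label -> dominating accession id),
#'   `order` (the optimized [priority_order]), `grid`, `accessions`,
#'   `groups`, `fit`, `threshold`, `smoothing` (parameters and number of
#'   reassigned cells), `transitions`, and `call`.
#' @examples
#' demo <- demo_mosaic()
#' fit <- introblocker(demo$wd, groups = demo$groups)
#' fit
#' @export
introblocker <- function(wd, grid = NULL, depth = NULL, threshold = 1e-3,
                         groups = NULL, smooth = TRUE, fit = NULL,
                         flank = 10, ratio = 10, coverage = 0.95,
                         cnv_low = 0.5, cnv_high = 1.5,
                         n_fit_pairs = 1000, seed = 1) {
  cl <- match.call()
  if (inherits(wd, "genotype_matrix")) {
    if (is.null(grid)) stop("grid is required when passing a genotype matrix")
    wd <- pairwise_window_distances(wd, grid)
  }
  grid <- wd$grid
  accs <- wd$accessions
  n <- length(accs); nw <- nrow(grid)
  mask <- matrix(MASK_OK, n, nw, dimnames = list(accs, window_names(grid)))
  if (!is.null(depth)) {
    if (!all(accs %in% rownames(depth)))
      stop("depth matrix does not cover all accessions")
    cnv <- cnv_blocks(depth[accs, , drop = FALSE], cnv_low, cnv_high)
    mask[cnv] <- MASK_CNV
  }
  mask[, wd$nodata] <- MASK_NODATA

  ic <- binwise_cluster(wd, threshold, mask)

  if (is.null(groups)) {
    initial <- select_core_accessions(ic, coverage)
    ord <- optimize_order(ic, initial, chrom = grid$chrom)
  } else {
    miss <- setdiff(accs, names(groups$groups))
    if (length(miss)) stop("accessions without group: ", paste(miss, collapse = ", "))
    blocks <- lapply(groups$group_order, function(g) {
      members <- accs[groups$groups[accs] == g]
      if (!length(members)) return(character(0))
      select_core_accessions(ic[members, , drop = FALSE], coverage)
    })
    ord <- optimize_order(ic, unlist(blocks), groups = groups,
                          chrom = grid$chrom)
  }

  labels <- assign_ahgs_rank(ic, match(accs, ord$order))

  smoothing <- list(applied = FALSE, flank = flank, ratio = ratio,
                    n_changed = 0L)
  if (smooth) {
    if (is.null(fit)) {
      vals <- sample_pair_distances(wd, n_fit_pairs, seed)
      fit <- fit_distance_mixture(vals, n_components = 2, seed = seed)
    }
    sm <- bayesian_smooth(labels, wd, fit, flank = flank, ratio = ratio,
                          mask = mask, chrom = grid$chrom)
    labels <- sm$labels
    smoothing <- list(applied = TRUE, flank = flank, ratio = ratio,
                      n_changed = sum(sm$changed))
  }

  # renumber labels densely by priority rank of the dominating accession
  doms <- sort(unique(labels[!is.na(labels)]))
  doms <- doms[order(match(accs[doms], ord$order))]
  relab <- integer(n); relab[doms] <- seq_along(doms)
  out <- labels
  out[!is.na(labels)] <- relab[labels[!is.na(labels)]]

  structure(list(labels = out, mask = mask,
                 dominator = accs[doms],
                 order = ord, grid = grid, accessions = accs,
                 groups = groups, fit = fit, threshold = threshold,
                 smoothing = smoothing,
                 transitions = count_transitions(out, grid$chrom),
                 call = cl),
            class = "introblocker")
}

# pooled positive distances from up to n_pairs randomly chosen accession
# pairs, all windows; used for the internal mixture fit
sample_pair_distances <- function(wd, n_pairs = 1000, seed = 1) {
  n <- length(wd$accessions)
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  set.seed(seed)
  if (nrow(all_pairs) > n_pairs)
    all_pairs <- all_pairs[sample.int(nrow(all_pairs), n_pairs), , drop = FALSE]
  vals <- unlist(lapply(which(!wd$nodata), function(w)
    wd$D[, , w][all_pairs]))
  vals[vals > 0]
}

#' @export
print.introblocker <- function(x, ...) {
  cat(sprintf("IntroBlocker fit: %d accessions x %d windows, %d AHG labels\n",
              nrow(x$labels), ncol(x$labels), length(x$dominator)))
  cat(sprintf("  threshold %.3g variants/bp, %s order, %d transitions\n",
              x$threshold, x$order$mode, x$transitions))
  if (x$smoothing$applied)
    cat(sprintf("  smoothing: flank %d, ratio %g, %d cell(s) reassigned\n",
                x$smoothing$flank, x$smoothing$ratio, x$smoothing$n_changed))
  masked <- sum(x$mask != MASK_OK)
  if (masked) cat(sprintf("  %d masked cell(s) (CNV or no data)\n", masked))
  invisible(x)
}

#' @export
summary.introblocker <- function(object, ...) {
  lab <- object$labels
  per_window <- apply(lab, 2, function(v) length(unique(v[!is.na(v)])))
  dom_counts <- table(factor(object$labels, levels = seq_along(object$dominator)))
  res <- list(n_accessions = nrow(lab), n_windows = ncol(lab),
              n_labels = length(object$dominator),
              labels_per_window = summary(per_window),
              transitions = object$transitions,
              dominators = setNames(as.integer(dom_counts), object$dominator),
              order = object$order)
  class(res) <- "summary.introblocker"
  res
}

#' @export
print.summary.introblocker <- function(x, ...) {
  cat(sprintf("IntroBlocker fit: %d accessions x %d windows\n",
              x$n_accessions, x$n_windows))
  cat(sprintf("  %d AHG labels, %d transitions\n", x$n_labels, x$transitions))
  cat("  labels per window:\n")
  print(x$labels_per_window)
  cat("  top dominating accessions (cells carrying their label):\n")
  top <- sort(x$dominators, decreasing = TRUE)
  print(head(top, 5))
  invisible(x)
}

#' Extract the AHG label matrix
#'
#' @param x an [introblocker()] fit.
#' @param masked value to place in masked cells (`NA` default).
#' @return Integer accession x window matrix.
#' @export
ahg_map <- function(x, masked = NA_integer_) {
  m <- x$labels
  m[x$mask != MASK_OK] <- masked
  m
}

#' Canonical within-window partitions
#'
#' Returns, for every window, the partition of accessions induced by the
#' AHG labels in a label-free canonical form (clusters numbered by first
#' appearance).  Two fits agree on a window's ancestry structure iff these
#' vectors are identical, regardless of which accessions dominate the
#' labels — the formal sense in which the priority order changes naming,
#' never structure.
#'
#' @param x an [introblocker()] fit.
#' @return List of integer vectors, one per window (`NA` for masked cells).
#' @export
ahg_partitions <- function(x) {
  lapply(seq_len(ncol(x$labels)), function(w) {
    v <- x$labels[, w]
    idx <- match(v, unique(v[!is.na(v)]))
    names(idx) <- rownames(x$labels)
    idx
  })
}

#' @export
plot.introblocker <- function(x, ..., main = "AHG mosaic") {
  lab <- x$labels
  k <- length(x$dominator)
  pal <- grDevices::hcl.colors(max(k, 2), "Spectral")
  img <- t(lab[nrow(lab):1, , drop = FALSE])
  graphics::image(seq_len(ncol(lab)), seq_len(nrow(lab)), img,
                  col = pal, zlim = c(1, k), xlab = "window",
                  ylab = "accession", yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_len(nrow(lab)),
                 labels = rev(rownames(lab)), las = 2, cex.axis = 0.6)
  msk <- which(t(x$mask[nrow(lab):1, , drop = FALSE]) != MASK_OK, arr.ind = TRUE)
  if (nrow(msk))
    graphics::points(msk[, 1], msk[, 2], pch = 15, col = "black", cex = 0.8)
  invisible(x)
}

#' Persist / restore an AHG map as TSV
#'
#' Rows are accessions, columns windows (`chrom:start-end`); masked cells
#' hold the sentinels `CNV` or `NODATA`.  A `#`-prefixed provenance header
#' records threshold, mode, order and smoothing parameters, enough to
#' re-run the producing command.
#'
#' @param x an [introblocker()] fit.
#' @param path output path.
#' @return `path` invisibly; `read_ahg_tsv` returns a list with `labels`,
#'   `mask` and the provenance lines.
#' @export
write_ahg_tsv <- function(x, path) {
  m <- matrix(as.character(x$labels), nrow = nrow(x$labels),
              dimnames = dimnames(x$labels))
  m[x$mask == MASK_CNV] <- "CNV"
  m[x$mask == MASK_NODATA] <- "NODATA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# introblocker ahg map"),
    sprintf("# threshold=%.6g mode=%s flank=%d ratio=%g smoothed=%s",
            x$threshold, x$order$mode, x$smoothing$flank, x$smoothing$ratio,
            x$smoothing$applied),
    sprintf("# order=%s", paste(x$order$order, collapse = ",")),
    sprintf("# dominators=%s", paste(x$dominator, collapse = ","))), con)
  df <- data.frame(accession = rownames(m), m, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_ahg_tsv
#' @export
read_ahg_tsv <- function(path) {
  lines <- readLines(path)
  prov <- lines[startsWith(lines, "#")]
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$accession
  mask <- matrix(MASK_OK, nrow(m), ncol(m), dimnames = dimnames(m))
  mask[m == "CNV"] <- MASK_CNV
  mask[m == "NODATA"] <- MASK_NODATA
  labels <- suppressWarnings(matrix(as.integer(m), nrow(m),
                                    dimnames = dimnames(m)))
  list(labels = labels, mask = mask, provenance = prov)
}
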