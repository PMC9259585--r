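#' Per-window hierarchical clustering of accessions
#'
#' Step 1 of the AHG inference: for each window, accessions are clustered
#' by average-linkage hierarchical clustering of the binwise distance
#' matrix and the dendrogram is cut at the ancestry threshold, yielding
#' window-local initial AHG labels.  Masked cells (CNV or no-data) are
#' excluded from the window's dendrogram rather than clustered and then
#' masked: depth-aberrant windows violate the distance model.
#'
#' @param wd a [pairwise_window_distances()] object.
#' @param threshold cut height in variants/bp (> 0).
#' @param mask optional accession x window matrix of mask codes (0 = OK,
#'   1 = CNV, 2 = no data); non-zero cells are excluded.
#' @return An `initial_clusters` object: integer matrix accession x window
#'   of window-local cluster ids (`NA` where masked), with attributes
#'   `linkage = "average"` and `threshold`.
#' @export
binwise_cluster <- function(wd, threshold, mask = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(wd$accessions)
  nw <- dim(wd$D)[3]
  out <- matrix(NA_integer_, n, nw,
                dimnames = list(wd$accessions, dimnames(wd$D)[[3]]))
  for (w in seq_len(nw)) {
    keep <- if (is.null(mask)) rep(TRUE, n) else mask[, w] == 0L
    if (wd$nodata[w]) keep[] <- FALSE
    m <- sum(keep)
    if (m == 0L) next
    if (m == 1L) { out[keep, w] <- 1L; next }
    d <- as.dist(wd$D[keep, keep, w])
    hc <- hclust(d, method = "average")
    out[keep, w] <- cutree(hc, h = threshold)
  }
  structure(out, linkage = "average", threshold = threshold,
            class = c("initial_clusters", "matrix", "array"))
}

#' Count adjacent-window label transitions
#'
#' The objective minimized when choosing the accession priority order:
#' the total, over accessions, of adjacent non-masked window pairs on the
#' same chromosome whose labels differ.  Masked cells are skipped and the
#' two flanking non-masked windows are compared directly; transitions are
#' never counted across chromosome boundaries.
#'
#' @param labels integer accession x window label matrix (`NA` = masked),
#'   or an [introblocker()] fit.
#' @param chrom character vector of per-window chromosome names (taken
#'   from the fit when one is given).
#' @return Integer transition count.
#' @export
count_transitions <- function(labels, chrom = NULL) {
  if (inherits(labels, "introblocker")) {
    chrom <- labels$grid$chrom
    labels <- labels$labels
  }
  if (is.null(chrom)) chrom <- rep("chr", ncol(labels))
  total <- 0L
  for (ch in unique(chrom)) {
    block <- labels[, chrom == ch, drop = FALSE]
    for (i in seq_len(nrow(block))) {
      v <- block[i, ]
      v <- v[!is.na(v)]
      if (length(v) > 1L) total <- total + sum(v[-1L] != v[-length(v)])
    }
  }
  total
}

#' Greedy core-accession selection
#'
#' Step 2.1: builds the head of the priority order by iteratively picking
#' the accession that co-clusters with the most not-yet-covered
#' (window, accession) cells.  Round one maximizes total co-clustering
#' mass with all other accessions; later rounds maximize newly covered
#' cells; selection stops once at least `coverage` of all non-masked cells
#' are covered (a cell is covered when its accession co-clusters, in that
#' window, with some selected accession, or is itself selected).  The
#' remaining accessions are appended in input order, making the result
#' deterministic; ties go to the earlier input position.
#'
#' @param ic an [binwise_cluster()] matrix.
#' @param coverage stopping fraction in (0, 1], default 0.95.
#' @return Character vector: all accessions, selected core first.
#' @export
select_core_accessions <- function(ic, coverage = 0.95) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  n <- nrow(ic)
  nw <- ncol(ic)
  accs <- rownames(ic)
  covered <- is.na(ic)            # masked cells do not need covering
  total <- sum(!covered)
  selected <- integer(0)
  avail <- seq_len(n)
  while (length(avail) && total > 0 && sum(covered) - (n * nw - total) < coverage * total) {
    best <- 0L; best_gain <- -1L
    for (a in avail) {
      gain <- 0L
      for (w in seq_len(nw)) {
        if (is.na(ic[a, w])) next
        gain <- gain + sum(!covered[, w] & !is.na(ic[, w]) & ic[, w] == ic[a, w])
      }
      if (gain > best_gain) { best_gain <- gain; best <- a }
    }
    selected <- c(selected, best)
    avail <- setdiff(avail, best)
    for (w in seq_len(nw)) {
      if (is.na(ic[best, w])) next
      covered[!is.na(ic[, w]) & ic[, w] == ic[best, w], w] <- TRUE
    }
    if (best_gain == 0L) break   # nothing new coverable
  }
  accs[c(selected, avail)]
}

#' Thread AHG labels under a priority order
#'
#' Step 2: deterministic global label assignment.  Within each window,
#' every accession takes the label of the highest-priority member of its
#' initial cluster; an accession that is itself the highest-priority
#' member of its cluster uses its own label, which it is said to dominate.
#' The top-priority accession therefore carries one uniform label across
#' all its windows, and within any window the induced partition of
#' accessions is exactly the initial clustering, whatever the order: the
#' order only decides which accession's label names each cluster.
#'
#' @param ic an [binwise_cluster()] matrix.
#' @param order character vector, a permutation of the accessions of `ic`
#'   in priority order (highest first).
#' @return Integer accession x window matrix; the label value is the row
#'   index of the dominating accession (`NA` where masked).
#' @export
assign_ahgs <- function(ic, order) {
  accs <- rownames(ic)
  if (!setequal(order, accs) || length(order) != length(accs))
    stop("order must be a permutation of the accessions")
  rank <- match(accs, order)
  assign_ahgs_rank(ic, rank)
}

# core threading on integer priority ranks; label = dominating row index
assign_ahgs_rank <- function(ic, rank) {
  n <- nrow(ic)
  out <- matrix(NA_integer_, n, ncol(ic), dimnames = dimnames(ic))
  o <- order(rank)
  for (w in seq_len(ncol(ic))) {
    cl <- ic[, w]
    co <- cl[o]
    keep <- !is.na(co) & !duplicated(co, incomparables = NA)
    if (!any(keep)) next
    reps <- integer(max(cl, na.rm = TRUE))
    reps[co[keep]] <- o[keep]
    ok <- !is.na(cl)
    out[ok, w] <- reps[cl[ok]]
  }
  out
}

#' Optimize the priority order by adjacent swaps
#'
#' Step 2.2: starting from the greedy order of
#' [select_core_accessions()], repeatedly sweeps over adjacent accession
#' pairs, swaps them, re-threads the labels and keeps the swap when the
#' total transition count decreases.  Sweeping continues until a full pass
#' makes no change, giving a local optimum of the adjacent-swap
#' neighborhood (the count is a non-increasing integer, so termination is
#' guaranteed).  In semi-supervised mode swaps never cross group
#' boundaries and the concatenation order of groups is fixed by the user.
#'
#' @param ic an [binwise_cluster()] matrix.
#' @param initial character vector, the starting order (highest first);
#'   in semi-supervised mode it must already be concatenated by group.
#' @param groups optional [group_assignment()]; when given, its
#'   `group_order` fixes the group blocks.
#' @param chrom per-window chromosome names for transition counting.
#' @return A `priority_order` object: list with `order`, `mode`,
#'   `group_order`, `transitions`.
#' @export
optimize_order <- function(ic, initial, groups = NULL, chrom = NULL) {
  accs <- rownames(ic)
  if (!setequal(initial, accs)) stop("initial must be a permutation of accessions")
  if (!is.null(groups) && is.null(groups$group_order))
    stop("semi-supervised mode requires a group order")
  if (is.null(chrom)) chrom <- rep("chr", ncol(ic))
  ord <- initial
  gvec <- if (is.null(groups)) rep("all", length(ord)) else
    unname(groups$groups[ord])
  score <- function(o) {
    count_transitions(assign_ahgs_rank(ic, match(accs, o)), chrom)
  }
  cur <- score(ord)
  repeat {
    improved <- FALSE
    for (i in seq_len(length(ord) - 1L)) {
      if (gvec[i] != gvec[i + 1L]) next   # never swap across group blocks
      cand <- ord
      cand[c(i, i + 1L)] <- cand[c(i + 1L, i)]
      s <- score(cand)
      if (s < cur) {
        ord <- cand
        gvec[c(i, i + 1L)] <- gvec[c(i + 1L, i)]  # same values; keep aligned
        cur <- s
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(list(order = ord,
                 mode = if (is.null(groups)) "unsupervised" else "semisupervised",
                 group_order = groups$group_order, transitions = cur),
            class = "priority_order")
}

#' @export
print.priority_order <- function(x, ...) {
  cat(sprintf("priority order (%s), %d accessions, %d transitions\n",
              x$mode, length(x$order), x$transitions))
  cat(" ", paste(head(x$order, 10), collapse = " > "),
      if (length(x$order) > 10) "..." else "", "\n")
  invisible(x)
}
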