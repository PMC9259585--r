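#' Bayesian smoothing of an AHG label matrix
#'
#' Step 3: corrects locally inconsistent cells using the fitted
#' two-component distance mixture.  For each non-masked cell with label
#' `g`, let `d` be the binwise distance from the cell's accession to the
#' accession dominating `g`.  Two error weights are computed on the log10
#' scale: `alpha`, the upper tail of the same-ancestry (low) component at
#' `d`, and `beta`, the lower tail of the different-ancestry (high)
#' component at `d`.  When `beta > ratio * alpha` the observed distance is
#' unusually large for shared ancestry relative to the different-ancestry
#' component, the hard-threshold call carries real information, and the
#' cell is left untouched.  Otherwise (notably every cell whose distance
#' to its representative is near zero, where `alpha ~ 1`) the cell is
#' re-scored against its neighborhood: the candidate set is every label
#' present among the flanking windows (`flank / 2` on each side,
#' truncated at chromosome ends) plus the incumbent, each scored as
#' `occurrences x w`, with occurrences counted over the flanks plus the
#' current cell and `w` the same-ancestry upper tail at the cell's
#' distance to the candidate's dominating accession.  Reassignment
#' asserts co-membership within the window, so a candidate must be
#' carried there by at least one other accession (otherwise it scores
#' zero); when its dominating accession is not among those carriers —
#' in particular when the cell itself dominates the label — the nearest
#' other in-window carrier stands in.  A candidate whose own distance
#' fails the same error test (its
#' `beta` exceeds `ratio` times its `alpha`, marking it different
#' ancestry) is inadmissible and scores zero.  The cell is reassigned to
#' the top-scoring label only when that label beats the incumbent's score
#' by more than the same factor `ratio` (ties and modest margins keep the
#' incumbent), so locally
#' supported assignments are stable while an isolated singleton label is
#' flipped to the best-supported neighboring type — the noise correction
#' this step exists for.  Candidates whose dominating accession is
#' masked in the window are skipped.
#'
#' @param labels integer label matrix from [assign_ahgs()] (values are
#'   dominating-accession row indices).
#' @param wd the [pairwise_window_distances()] the labels were built from.
#' @param fit a 2-component [fit_distance_mixture()].
#' @param flank total flanking window count (default 10, i.e. 5 per side).
#' @param ratio keep factor (default 10).
#' @param mask accession x window mask codes (0 = OK).
#' @param chrom per-window chromosome names.
#' @return List: `labels` (smoothed matrix) and `changed` (logical matrix
#'   of reassigned cells).  Only cells failing the keep test can change.
#' @export
bayesian_smooth <- function(labels, wd, fit, flank = 10, ratio = 10,
                            mask = NULL, chrom = NULL) {
  if (length(fit$mean) != 2L)
    stop("smoothing requires a 2-component mixture fit")
  if (is.null(chrom)) chrom <- wd$grid$chrom
  n <- nrow(labels); nw <- ncol(labels)
  if (is.null(mask)) mask <- matrix(MASK_OK, n, nw)
  half <- max(1L, floor(flank / 2))
  lo_tail <- function(d) {        # alpha / candidate weight: upper tail, low comp
    ifelse(d <= 0, 1, pnorm(log10(d), fit$mean[1], fit$sd[1], lower.tail = FALSE))
  }
  hi_tail <- function(d) {        # beta: lower tail, high comp
    ifelse(d <= 0, 0, pnorm(log10(d), fit$mean[2], fit$sd[2]))
  }
  out <- labels
  changed <- matrix(FALSE, n, nw, dimnames = dimnames(labels))
  # candidate weight: same-ancestry tail at the distance to the label's
  # dominating accession; when the cell itself dominates the label, the
  # self-distance is identically zero and carries no information, so the
  # nearest other in-window carrier stands in (no carrier: weight 0)
  cand_weight <- function(a, t, w) {
    # reassignment asserts in-window co-membership, so a candidate label
    # must be carried by some other accession in this window
    others <- which(!is.na(labels[, w]) & labels[, w] == t & seq_len(n) != a)
    if (!length(others)) return(0)
    dom <- t
    if (dom != a && mask[dom, w] != MASK_OK) return(-Inf)
    d <- if (dom != a && dom %in% others) wd$D[a, dom, w]
         else min(wd$D[a, others, w])
    # a type whose distance the error test itself rejects as
    # different-ancestry can never adopt the cell
    if (hi_tail(d) > ratio * lo_tail(d)) return(0)
    lo_tail(d)
  }
  for (w in seq_len(nw)) {
    same_chr <- which(chrom == chrom[w])
    fl <- same_chr[same_chr >= w - half & same_chr <= w + half & same_chr != w]
    for (a in seq_len(n)) {
      g <- labels[a, w]
      if (is.na(g) || mask[a, w] != MASK_OK) next
      d <- if (g == a) 0 else wd$D[a, g, w]
      if (hi_tail(d) > ratio * lo_tail(d)) next   # keep: beta > ratio * alpha
      cand <- labels[a, fl]
      cand <- c(cand[!is.na(cand)], g)           # incumbent counts its own cell
      occ <- table(cand)
      lab_ids <- as.integer(names(occ))
      score <- vapply(seq_along(lab_ids), function(k)
        as.numeric(occ[k]) * cand_weight(a, lab_ids[k], w), numeric(1))
      if (all(!is.finite(score) | score <= 0)) next
      best <- lab_ids[which.max(score)]
      inc <- match(g, lab_ids)
      # the incumbent is only displaced by decisively stronger support
      if (score[inc] * ratio >= max(score)) next
      if (best != g) { out[a, w] <- best; changed[a, w] <- TRUE }
    }
  }
  list(labels = out, changed = changed)
}
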