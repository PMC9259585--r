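#' Binwise pairwise genetic distances
#'
#' For every window of the grid, computes the symmetric accession-pair
#' distance in variants per bp: the sum of per-site mismatches divided by
#' the window length.  Site mismatch between dosages `a` and `b` is
#' `|a - b| / 2` (hom vs opposite hom = 1, het vs hom = 0.5), the
#' fractional identity-by-state distance of PLINK's `1-ibs`.  Sites where
#' either call is missing are skipped; the denominator stays the full
#' window length (the ancestry threshold is defined per bp of window, not
#' per callable site), unless `missing_rescale = TRUE`, which rescales the
#' mismatch sum by `window_length / co-called sites` x site count.
#'
#' @param gm a [genotype_matrix()].
#' @param grid a [make_windows()] grid covering the sites.
#' @param pairs optional character vector of accession ids to restrict to.
#' @param missing_rescale rescale by the callable fraction (default FALSE).
#' @return A `window_distances` object: list with `D` (3-d array
#'   accession x accession x window, variants/bp), `nsites` (variant count
#'   per window), `nodata` (windows with no sites), `grid`, `accessions`.
#' @export
pairwise_window_distances <- function(gm, grid, pairs = NULL,
                                      missing_rescale = FALSE) {
  calls <- gm$calls
  if (!is.null(pairs)) {
    bad <- setdiff(pairs, rownames(calls))
    if (length(bad)) stop("unknown accession(s): ", paste(bad, collapse = ", "))
    calls <- calls[pairs, , drop = FALSE]
  }
  widx <- site_window(grid, gm$chrom, gm$pos)
  if (anyNA(widx)) stop("some site positions fall outside the window grid")
  n <- nrow(calls)
  nw <- nrow(grid)
  D <- array(0, dim = c(n, n, nw),
             dimnames = list(rownames(calls), rownames(calls), window_names(grid)))
  nsites <- integer(nw)
  lens <- window_lengths(grid)
  for (w in seq_len(nw)) {
    sel <- which(widx == w)
    nsites[w] <- length(sel)
    if (!length(sel)) next
    mm <- mismatch_counts(calls[, sel, drop = FALSE], missing_rescale)
    D[, , w] <- mm / lens[w]
  }
  structure(list(D = D, nsites = nsites, nodata = nsites == 0L, grid = grid,
                 accessions = rownames(calls)),
            class = "window_distances")
}

# accession x accession mismatch sums for one window's dosage block.
# Crossprod decomposition: sum |a-b| over co-called sites equals
# sum (a-b)^2 minus 2 * (# opposite-homozygote sites), since
# |a-b| in {0,1,2} and (a-b)^2 in {0,1,4}.
mismatch_counts <- function(G, missing_rescale = FALSE) {
  ok <- !is.na(G)
  Gz <- G; Gz[!ok] <- 0L
  storage.mode(Gz) <- "double"
  okd <- ok; storage.mode(okd) <- "double"
  G2 <- Gz^2
  S2 <- tcrossprod(G2, okd) + tcrossprod(okd, G2) - 2 * tcrossprod(Gz)
  I0 <- (Gz == 0) & ok; storage.mode(I0) <- "double"
  I2 <- (Gz == 2) & ok; storage.mode(I2) <- "double"
  opp <- tcrossprod(I0, I2)
  mm <- (S2 - 2 * (opp + t(opp))) / 2
  if (missing_rescale) {
    co <- tcrossprod(okd)
    scale <- ncol(G) / co
    scale[co == 0] <- 0
    mm <- mm * scale
  }
  diag(mm) <- 0
  mm
}

#' @export
print.window_distances <- function(x, ...) {
  cat(sprintf("window distances: %d accessions, %d windows (%d without data)\n",
              length(x$accessions), length(x$nsites), sum(x$nodata)))
  invisible(x)
}

#' Persist window distances as long-format TSV
#'
#' One row per (window, pair): `chrom`, `start`, `end`, `acc1`, `acc2`,
#' `distance`.  Only the upper triangle is written.
#'
#' @param wd a [pairwise_window_distances()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distances_tsv <- function(wd, path) {
  n <- length(wd$accessions)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(wd$grid)), function(w) {
    data.frame(chrom = wd$grid$chrom[w], start = wd$grid$start[w],
               end = wd$grid$end[w],
               acc1 = wd$accessions[ut[, 1]], acc2 = wd$accessions[ut[, 2]],
               distance = wd$D[, , w][ut])
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Date a divergence from variant density
#'
#' Converts a genetic distance `D` (variants per bp) into a divergence time
#' `T = D / (2 mu)` in years, with `mu` the neutral per-nucleotide per-year
#' mutation rate (default 1.6e-8, the Triticeae estimate).
#'
#' @param D genetic distance(s) in variants/bp, `>= 0`.
#' @param mu mutation rate per nt per year, `> 0`.
#' @return Divergence time(s) in years.
#' @seealso [report_years()] for the nearest-hundred rounding used in text.
#' @examples
#' date_divergence(2.2e-4)            # 6875
#' report_years(date_divergence(2.2e-4))  # 6900
#' @export
date_divergence <- function(D, mu = 1.6e-8) {
  if (any(D < 0)) stop("D must be >= 0")
  if (length(mu) != 1L || is.na(mu) || mu <= 0) stop("mu must be > 0")
  D / (2 * mu)
}

#' @rdname date_divergence
#' @param years time(s) in years.
#' @export
report_years <- function(years) round(years / 100) * 100
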