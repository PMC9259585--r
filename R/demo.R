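#' Synthetic mosaic-ancestry demonstration cohort
#'
#' Builds a small, fully synthetic cohort of 11 accessions (4 wild emmer
#' "WE", 4 domesticated tetraploid "DT", 3 hexaploid "HW") over 20 windows
#' of one 100-Mbp chromosome, in which each window of each accession is
#' drawn from a small pool of ancestral haplotypes and binwise distances
#' are generated directly from the ancestry: pairs sharing a haplotype get
#' same-ancestry distances (around `3e-5` variants/bp), all other pairs
#' get different-ancestry distances (around `3e-3`), i.e. the two modes of
#' the wheat A&B log-distance distribution.  Deterministic given `seed`.
#'
#' Intended for examples and for checking structural properties of the
#' threading (e.g. that reversing the group priority changes label
#' domination but never the within-window partitions).
#'
#' @param seed integer seed.
#' @param n_windows number of windows (default 20).
#' @return List with `wd` ([pairwise_window_distances()]-shaped object),
#'   `truth` (accession x window ancestral haplotype ids), `groups`
#'   ([group_assignment()] with order WE > DT > HW), and `grid`.
#' @export
demo_mosaic <- function(seed = 42, n_windows = 20) {
  set.seed(seed)
  accs <- c(paste0("WE", 1:4), paste0("DT", 1:4), paste0("HW", 1:3))
  groups <- group_assignment(
    setNames(rep(c("WE", "DT", "HW"), c(4, 4, 3)), accs),
    c("WE", "DT", "HW"))
  n <- length(accs)
  grid <- make_windows(c(chr2A = n_windows * 5e6), 5e6)
  # ancestral haplotype pool: WE accessions are their own lineages; DT/HW
  # are mosaics over the WE lineages plus one haplotype absent from WE
  pool <- 1:5
  truth <- matrix(0L, n, n_windows, dimnames = list(accs, window_names(grid)))
  truth[1:4, ] <- matrix(rep(1:4, n_windows), 4)    # WE: uniform lineages
  for (a in 5:n) {
    # segment the chromosome into a few runs with lineage switches
    n_seg <- sample(2:5, 1)
    cuts <- sort(sample(2:(n_windows - 1), n_seg - 1))
    bounds <- c(1, cuts, n_windows + 1)
    for (s in seq_len(n_seg)) {
      truth[a, bounds[s]:(bounds[s + 1] - 1)] <- sample(pool, 1)
    }
  }
  D <- array(0, dim = c(n, n, n_windows),
             dimnames = list(accs, accs, window_names(grid)))
  for (w in seq_len(n_windows)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      same <- truth[i, w] == truth[j, w]
      d <- if (same) 10^rnorm(1, log10(3e-5), 0.1)
           else 10^rnorm(1, log10(3e-3), 0.1)
      D[i, j, w] <- D[j, i, w] <- d
    }
  }
  wd <- structure(list(D = D, nsites = rep(1000L, n_windows),
                       nodata = rep(FALSE, n_windows), grid = grid,
                       accessions = accs),
                  class = "window_distances")
  list(wd = wd, truth = truth, groups = groups, grid = grid)
}
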