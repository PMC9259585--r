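# shared fixture builders; everything is generated in code at test time

# minimal VCF text fixture: 3 samples, 5 biallelic + 1 triallelic site
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a1", "a2", "a3", sep = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t./.",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t1/2\t2/2",   # triallelic
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0",
    "chr1\t500\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",    # indel
    "chr1\t600\t.\tG\tC\t.\tPASS\t.\tGT\t./1\t0/0\t1/1"      # half call
  )
  writeLines(lines, path)
  path
}

random_gm <- function(n_acc = 4, n_sites = 200, chrom_len = 1e6,
                      missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_sites))
  calls <- matrix(sample(0:2, n_acc * n_sites, replace = TRUE),
                  nrow = n_acc)
  calls[matrix(runif(length(calls)) < missing_rate, nrow = n_acc)] <- NA
  rownames(calls) <- paste0("acc", seq_len(n_acc))
  genotype_matrix(calls, rep("chr1", n_sites), pos)
}

# site-by-site mismatch oracle, deliberately naive
brute_window_distances <- function(gm, grid) {
  n <- nrow(gm$calls)
  nw <- nrow(grid)
  D <- array(0, dim = c(n, n, nw))
  for (w in seq_len(nw)) {
    insel <- gm$chrom == grid$chrom[w] & gm$pos > grid$start[w] &
      gm$pos <= grid$end[w]
    len <- grid$end[w] - grid$start[w]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (k in which(insel)) {
        a <- gm$calls[i, k]; b <- gm$calls[j, k]
        if (!is.na(a) && !is.na(b)) s <- s + abs(a - b) / 2
      }
      D[i, j, w] <- s / len
    }
  }
  D
}

# naive average-linkage clustering cut at height h (independent of hclust)
brute_average_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# canonical form of a partition vector (labels by first appearance)
canon <- function(v) match(v, unique(v[!is.na(v)]))

# random initial-cluster matrix
random_ic <- function(n_acc, nw, k = 3, seed = 1, mask_rate = 0) {
  set.seed(seed)
  m <- matrix(sample.int(k, n_acc * nw, replace = TRUE), n_acc, nw)
  if (mask_rate > 0)
    m[matrix(runif(length(m)) < mask_rate, n_acc)] <- NA
  rownames(m) <- paste0("acc", seq_len(n_acc))
  structure(m, linkage = "average", threshold = 1e-3,
            class = c("initial_clusters", "matrix", "array"))
}

# window_distances object built directly from a distance array
wd_from_array <- function(D, window_size = 5e6, chrom = "chr1") {
  n <- dim(D)[1]; nw <- dim(D)[3]
  accs <- dimnames(D)[[1]]
  if (is.null(accs)) {
    accs <- paste0("acc", seq_len(n))
    dimnames(D) <- list(accs, accs, NULL)
  }
  grid <- make_windows(setNames(nw * window_size, chrom), window_size)
  dimnames(D)[[3]] <- introblocker:::window_names(grid)
  structure(list(D = D, nsites = rep(100L, nw), nodata = rep(FALSE, nw),
                 grid = grid, accessions = accs),
            class = "window_distances")
}

# small, fast simulation configuration for unit tests
tiny_cfg <- function(n_sources = 2, seed = 1, ...) {
  sim_config(n_sources = n_sources, source_ne = 60, source_samples = 8,
             target_samples = 20, chrom_length = 4e6, segment_length = 1e6,
             total_generations = 40, admix_generation = 12, seed = seed, ...)
}
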