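#' Tile chromosomes into non-overlapping genomic windows
#'
#' Builds the window grid on which all binwise statistics are computed.
#' Windows are half-open, 0-based `[start, end)` intervals of fixed size;
#' the last window of a chromosome is truncated to the chromosome length.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_size window size in bp (default 5 Mbp, chosen to exceed the
#'   typical linkage-disequilibrium decay distance of a selfing cereal; set
#'   it per organism).
#' @return A `window_grid` object: a data.frame with columns `chrom`,
#'   `start`, `end` and attributes `window_size` and `chrom_lengths`.
#' @examples
#' make_windows(c(chr1 = 12e6), 5e6)
#' @export
make_windows <- function(chrom_lengths, window_size = 5e6) {
  if (length(window_size) != 1L || is.na(window_size) || window_size <= 0)
    stop("window_size must be a single positive number")
  if (length(chrom_lengths) == 0L || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be > 0")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n <- ceiling(len / window_size)
    start <- (seq_len(n) - 1) * window_size
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(grid, window_size = window_size, chrom_lengths = chrom_lengths,
            class = c("window_grid", "data.frame"))
}

#' @export
print.window_grid <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("window grid: %d windows of %s bp over %d chromosome(s)\n",
              nrow(x), format(attr(x, "window_size"), big.mark = ","),
              length(cl)))
  invisible(x)
}

window_names <- function(grid) {
  sprintf("%s:%d-%d", grid$chrom, as.integer(grid$start), as.integer(grid$end))
}

window_lengths <- function(grid) grid$end - grid$start

#' Export a window grid as BED3
#'
#' @param grid a [make_windows()] grid.
#' @param path output path; BED is 0-based half-open, matching the internal
#'   window convention, so coordinates are written unchanged.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(grid, path) {
  write.table(data.frame(grid$chrom, as.integer(grid$start), as.integer(grid$end)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# window index for 1-based site positions on one chromosome; NA outside grid
site_window <- function(grid, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- which(grid$chrom == ch)
    if (!length(g)) next
    # positions are 1-based: site p lies in [start, end) iff start < p <= end
    w <- findInterval(pos[sel] - 1L, grid$start[g])
    w[w < 1L | (pos[sel] - 1L) >= grid$end[g][pmax(w, 1L)]] <- NA_integer_
    idx[sel] <- g[w]
  }
  idx
}
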