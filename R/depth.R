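#' Normalized per-window read depth
#'
#' Reads a long-format depth table (columns `accession`, `chrom`, `start`,
#' `end`, `depth`; `start`/`end` 0-based half-open, matching the grid) and
#' returns an accession x window matrix normalized so that each accession's
#' mean depth over a reference window set equals 1.  The reference set
#' defaults to all windows; for an allopolyploid it would typically be the
#' windows of the well-behaved subgenomes (e.g. A&B in wheat), passed as
#' `normalization_windows`.
#'
#' @param depth_table data.frame or TSV path with the columns above.
#' @param grid a [make_windows()] grid.
#' @param normalization_windows optional integer indices (rows of `grid`)
#'   over which per-accession means are normalized to 1.
#' @return A `depth_matrix`: numeric matrix accessions x windows with
#'   column names `chrom:start-end`, all values >= 0, attribute
#'   `normalization_windows`.
#' @export
window_depth <- function(depth_table, grid, normalization_windows = NULL) {
  if (is.character(depth_table))
    depth_table <- read.table(depth_table, header = TRUE, sep = "\t",
                              check.names = FALSE)
  need <- c("accession", "chrom", "start", "end", "depth")
  if (!all(need %in% names(depth_table)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  wn <- window_names(grid)
  key <- sprintf("%s:%d-%d", depth_table$chrom,
                 as.integer(depth_table$start), as.integer(depth_table$end))
  accs <- unique(depth_table$accession)
  m <- matrix(NA_real_, nrow = length(accs), ncol = length(wn),
              dimnames = list(accs, wn))
  m[cbind(match(depth_table$accession, accs), match(key, wn))] <-
    depth_table$depth
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    stop("depth table is missing window rows, e.g.: ",
         paste(head(paste(rownames(m)[gaps[, 1]], wn[gaps[, 2]], sep = " @ "), 5),
               collapse = "; "))
  }
  if (any(m < 0)) stop("depth values must be >= 0")
  if (is.null(normalization_windows)) normalization_windows <- seq_along(wn)
  ref_mean <- rowMeans(m[, normalization_windows, drop = FALSE])
  if (any(ref_mean <= 0)) stop("an accession has zero mean reference depth")
  m <- m / ref_mean
  structure(m, normalization_windows = normalization_windows,
            class = c("depth_matrix", "matrix", "array"))
}

#' Call CNV blocks from normalized depth
#'
#' A window of an accession is flagged as a copy-number-variant (CNV) block
#' when its normalized depth leaves the `(low, high)` band; the bounds are
#' strict, so depths of exactly `low` or `high` are not CNV.  The mask is
#' used both to exclude depth-aberrant windows from AHG clustering (the
#' distance model assumes a single diploid copy) and as input to the
#' CNV-enriched-block scan ([ceb_scan()]).
#'
#' @param depth a [window_depth()] matrix (or any normalized accession x
#'   window matrix).
#' @param low,high strict bounds on normalized depth (defaults 0.5 / 1.5).
#' @return Logical matrix, `TRUE` where the cell is a CNV block.
#' @export
cnv_blocks <- function(depth, low = 0.5, high = 1.5) {
  m <- unclass(depth) < low | unclass(depth) > high
  structure(m, dimnames = dimnames(depth))
}

#' Group assignment of accessions
#'
#' Binds each accession to exactly one group (e.g. the domestication stages
#' WE, DT, LR, CV) together with the ordered group priority list used in
#' semi-supervised label threading and staged scans.
#'
#' @param groups named character vector, accession id -> group label.
#' @param group_order character vector giving group priority, highest
#'   first; must cover every label present.
#' @return A `group_assignment` object (list with `groups`, `group_order`).
#' @export
group_assignment <- function(groups, group_order = unique(unname(groups))) {
  if (is.null(names(groups))) stop("groups must be named by accession")
  if (anyDuplicated(names(groups))) stop("each accession must appear once")
  missing_groups <- setdiff(unique(groups), group_order)
  if (length(missing_groups))
    stop("group_order does not cover: ", paste(missing_groups, collapse = ", "))
  structure(list(groups = groups, group_order = group_order),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(factor(x$groups, levels = x$group_order))
  cat("group assignment:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = " > "), "\n")
  invisible(x)
}
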