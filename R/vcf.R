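#' Construct a genotype matrix
#'
#' The genotype container used throughout the package: biallelic sites as
#' diploid dosages in `{0, 1, 2}` with `NA` for missing calls.  Positions
#' follow the VCF convention (1-based) and must be strictly increasing
#' within each chromosome.
#'
#' @param calls integer matrix, accessions in rows and sites in columns,
#'   values in `{0, 1, 2, NA}`; rownames are accession ids.
#' @param chrom character vector of per-site chromosome names.
#' @param pos integer vector of per-site 1-based positions.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, chrom, pos) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop("calls must have accession rownames")
  if (anyDuplicated(rownames(calls))) stop("accession ids must be unique")
  if (length(chrom) != ncol(calls) || length(pos) != ncol(calls))
    stop("chrom/pos length must equal the number of sites")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("calls must be dosages in {0, 1, 2} or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(calls = calls, chrom = as.character(chrom),
                 pos = as.integer(pos)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d accessions x %d biallelic sites (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(unique(x$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

accessions <- function(gm) rownames(gm$calls)

#' Read genotypes from a VCF file
#'
#' Reads a VCF (plain or bgzipped), keeps biallelic sites only, and
#' collapses diploid GT calls to dosages: `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`; half calls and `./.` become missing.  Multi-allelic sites
#' are dropped rather than split because mismatch counting is only defined
#' for biallelic dosages.  Indels are retained and treated like SNPs: a
#' site either matches between two accessions or it does not.  Upstream
#' quality filtering (caller annotations, depth bounds) is assumed done.
#'
#' @param path VCF file path.
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction,
#'   1-based inclusive coordinates.
#' @param samples optional character vector of sample ids to keep.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & alt != "." & !grepl(",", alt, fixed = TRUE)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- keep & chrom == r$chrom
    if (!is.na(r$start)) keep <- keep & pos >= r$start & pos <= r$end
  }
  gt <- v@gt[keep, -1L, drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  ids <- colnames(gt)
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, ids)
    if (length(missing_ids))
      stop("sample id(s) not in VCF: ", paste(missing_ids, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
    ids <- samples
  }
  gtfield <- sub(":.*$", "", gt)  # GT is the first FORMAT field per spec 4.x
  dosage <- gt_to_dosage(gtfield)
  calls <- t(matrix(dosage, nrow = nrow(gt), ncol = ncol(gt)))
  rownames(calls) <- ids
  genotype_matrix(calls, chrom, pos)
}

parse_region <- function(region) {
  if (is.list(region)) return(region)
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop("malformed region: ", region)
  list(chrom = m[2],
       start = if (m[4] == "") NA_integer_ else as.integer(m[4]),
       end = if (m[5] == "") NA_integer_ else as.integer(m[5]))
}

gt_to_dosage <- function(gt) {
  a <- sub("^([^/|]*)[/|]([^/|]*)$", "\\1,\\2", gt)
  parts <- strsplit(a, ",", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".") || any(!p %in% c("0", "1")))
      return(NA_integer_)
    sum(p == "1")
  }, integer(1))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Serializes dosages back to diploid GT records (REF/ALT are placeholder
#' alleles when the matrix does not carry real ones, as for simulated
#' cohorts).  The output is plain-text VCF 4.2 with GT only.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param provenance optional character vector written as `##` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, provenance = NULL) {
  ids <- accessions(gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introblocker",
               if (!is.null(provenance)) paste0("##", provenance),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  gtxt <- matrix("./.", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gtxt[ok] <- code[gm$calls[ok] + 1L]
  lines <- paste(gm$chrom, gm$pos, ".", "A", "T", ".", "PASS", ".", "GT",
                 sep = "\t")
  body <- paste(lines, apply(gtxt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write / read per-site dosage tables
#'
#' Plain TSV persistence for genotype matrices: columns `chrom`, `pos`,
#' then one column per accession with dosages (`NA` for missing).  The
#' round trip is exact.
#'
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(gm, path) {
  df <- data.frame(chrom = gm$chrom, pos = gm$pos, t(gm$calls),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  calls <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  genotype_matrix(calls, df$chrom, df$pos)
}
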