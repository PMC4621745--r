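#' Define a genome as an ordered list of chromosomes
#'
#' A genome definition is the coordinate frame for every other object in the
#' package: rearrangement breakpoints and copy-number segments are validated
#' against it, and it supplies the denominator of fraction-of-genome-altered
#' computations.
#'
#' @param chrom character vector of unique chromosome names.
#' @param chrom_length numeric vector of chromosome lengths in bases
#'   (strictly positive).
#' @return A `data.frame` of class `genome_def` with columns `chrom` and
#'   `length`, in the order given.
#' @examples
#' genome_def(c("chr1", "chr2"), c(60e6, 40e6))
#' @export
genome_def <- function(chrom, chrom_length) {
  chrom <- as.character(chrom)
  chrom_length <- as.numeric(chrom_length)
  if (length(chrom) != length(chrom_length)) {
    stop("`chrom` and `chrom_length` must have the same length", call. = FALSE)
  }
  if (length(chrom) == 0L) stop("genome must have at least one chromosome", call. = FALSE)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (any(!is.finite(chrom_length)) || any(chrom_length <= 0)) {
    stop("chromosome lengths must be positive and finite", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length = chrom_length, stringsAsFactors = FALSE)
  class(out) <- c("genome_def", "data.frame")
  out
}

#' Read a genome definition from a two-column TSV
#'
#' @param path TSV file with a header and columns `chrom`, `length`.
#' @return A [genome_def()] object.
#' @export
read_genome_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "length")
  if (!all(need %in% names(df))) {
    stop("genome TSV must have columns 'chrom' and 'length': ", path, call. = FALSE)
  }
  genome_def(df$chrom, df$length)
}

#' Write a genome definition as TSV
#' @param genome a [genome_def()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_tsv <- function(genome, path) {
  write_tsv_with_meta(as.data.frame(genome), path)
  invisible(path)
}

# Sex (and mitochondrial) chromosomes, with or without a "chr" prefix.
is_sex_chrom <- function(chrom) {
  grepl("^(chr)?(X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

#' Total genome length
#'
#' @param genome a [genome_def()] object.
#' @param include_sex include sex/mitochondrial chromosomes (default `FALSE`,
#'   the conventional autosome-only denominator for burden fractions).
#' @return total length in bases of the included chromosomes.
#' @export
genome_total_length <- function(genome, include_sex = FALSE) {
  stopifnot(inherits(genome, "genome_def"))
  keep <- if (include_sex) rep(TRUE, nrow(genome)) else !is_sex_chrom(genome$chrom)
  if (!any(keep)) stop("no chromosomes left after excluding sex chromosomes", call. = FALSE)
  sum(genome$length[keep])
}

# Validate chromosome names against a genome definition.
check_chroms <- function(chrom, genome, what = "record") {
  bad <- setdiff(unique(chrom), genome$chrom)
  if (length(bad)) {
    stop(sprintf("%s refers to chromosome(s) not in the genome definition: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

chrom_length_of <- function(genome, chrom) {
  genome$length[match(chrom, genome$chrom)]
}
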