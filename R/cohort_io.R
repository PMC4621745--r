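# Readers and writers for the cohort file formats, and the single place
# where coordinate conventions are fixed:
#   * BEDPE on disk: 0-based half-open (both end intervals).
#   * SEG and mutation TSV on disk: 1-based inclusive.
#   * Everything internal: 0-based half-open.
# The breakpoint position of a BEDPE end interval is its start coordinate
# (end intervals are typically 1 bp; a single representative point is needed
# for ordering).

#' Read structural rearrangements from a BEDPE file
#'
#' Expects at least the canonical ten columns
#' (chrom1, start1, end1, chrom2, start2, end2, name, score, strand1, strand2).
#' The sample identifier is taken from the `name` column unless `sample_id`
#' overrides it for the whole file. For intrachromosomal events the two ends
#' are stored in sorted order (`pos_a <= pos_b`), swapping strands along with
#' positions.
#'
#' @param path BEDPE file path; lines beginning with `#` or `track` are skipped.
#' @param genome a [genome_def()]; records on unknown chromosomes are rejected.
#' @param sample_id optional sample id applied to every record, overriding the
#'   name column.
#' @return data.frame with columns `sample_id`, `chrom_a`, `pos_a`,
#'   `strand_a`, `chrom_b`, `pos_b`, `strand_b`, `subtype` (`NA` until
#'   classified by [classify_events()]).
#' @export
read_rearrangements <- function(path, genome, sample_id = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_rearrangements())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    i <- which(nf < 10L)[1L]
    stop(sprintf("malformed BEDPE line %d in %s: %d field(s), expected >= 10",
                 lineno[i], path, nf[i]), call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:10], character(10)))
  pos_a <- suppressWarnings(as.numeric(m[, 2]))
  pos_b <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(pos_a) || anyNA(pos_b)) {
    i <- which(is.na(pos_a) | is.na(pos_b))[1L]
    stop(sprintf("malformed BEDPE line %d in %s: non-numeric coordinate",
                 lineno[i], path), call. = FALSE)
  }
  ev <- data.frame(
    sample_id = if (is.null(sample_id)) m[, 7] else rep(sample_id, nrow(m)),
    chrom_a = m[, 1], pos_a = pos_a, strand_a = m[, 9],
    chrom_b = m[, 4], pos_b = pos_b, strand_b = m[, 10],
    subtype = NA_character_, stringsAsFactors = FALSE
  )
  check_chroms(c(ev$chrom_a, ev$chrom_b), genome, "BEDPE record")
  check_strands(c(ev$strand_a, ev$strand_b))
  sort_event_ends(ev)
}

empty_rearrangements <- function() {
  data.frame(sample_id = character(), chrom_a = character(), pos_a = numeric(),
             strand_a = character(), chrom_b = character(), pos_b = numeric(),
             strand_b = character(), subtype = character(),
             stringsAsFactors = FALSE)
}

check_strands <- function(strand) {
  bad <- setdiff(unique(strand), c("+", "-"))
  if (length(bad)) {
    stop("strand values must be '+' or '-'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Enforce the invariant pos_a <= pos_b for same-chromosome events.
sort_event_ends <- function(ev) {
  swap <- ev$chrom_a == ev$chrom_b & ev$pos_a > ev$pos_b
  if (any(swap)) {
    tmp <- ev[swap, c("pos_a", "strand_a")]
    ev$pos_a[swap] <- ev$pos_b[swap]
    ev$strand_a[swap] <- ev$strand_b[swap]
    ev$pos_b[swap] <- tmp$pos_a
    ev$strand_b[swap] <- tmp$strand_a
  }
  ev
}

#' Write rearrangements as ten-column BEDPE
#'
#' Inverse of [read_rearrangements()]: 1-bp end intervals, sample id in the
#' name column, `.` score.
#'
#' @param events rearrangement data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(events, path) {
  out <- data.frame(events$chrom_a, format_coord(events$pos_a),
                    format_coord(events$pos_a + 1),
                    events$chrom_b, format_coord(events$pos_b),
                    format_coord(events$pos_b + 1),
                    events$sample_id, ".", events$strand_a, events$strand_b,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read copy-number segments from a SEG file
#'
#' SEG files carry a header and columns sample, chrom, start, end, optionally
#' a marker count, and a segment mean (log2 tumor/normal ratio) as the last
#' column. On-disk coordinates are 1-based inclusive and are converted to the
#' internal 0-based half-open convention. Segments of one sample on one
#' chromosome must not overlap.
#'
#' @param path SEG file path.
#' @param genome a [genome_def()].
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `log2_ratio`.
#' @export
read_segments <- function(path, genome) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(empty_segments())
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) return(empty_segments())
  if (ncol(df) < 5L) stop("SEG file must have at least 5 columns: ", path, call. = FALSE)
  seg <- data.frame(
    sample_id = as.character(df[[1]]),
    chrom = as.character(df[[2]]),
    start = as.numeric(df[[3]]) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(df[[4]]),
    log2_ratio = as.numeric(df[[ncol(df)]]),
    stringsAsFactors = FALSE
  )
  validate_segments(seg, genome)
  seg
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), log2_ratio = numeric(), stringsAsFactors = FALSE)
}

#' Validate a segment table
#'
#' Checks coordinates, chromosome membership, and the per-sample
#' per-chromosome non-overlap invariant.
#'
#' @param segments segment data.frame (internal convention).
#' @param genome a [genome_def()].
#' @return `segments`, invisibly.
#' @export
validate_segments <- function(segments, genome) {
  if (nrow(segments) == 0L) return(invisible(segments))
  check_chroms(segments$chrom, genome, "segment")
  if (any(segments$start < 0) || any(segments$start >= segments$end)) {
    stop("segments must satisfy 0 <= start < end", call. = FALSE)
  }
  too_long <- segments$end > chrom_length_of(genome, segments$chrom)
  if (any(too_long)) {
    stop("segment extends beyond chromosome end (sample ",
         segments$sample_id[which(too_long)[1]], ")", call. = FALSE)
  }
  by_sc <- split(segments, list(segments$sample_id, segments$chrom), drop = TRUE)
  for (grp in by_sc) {
    o <- order(grp$start)
    if (any(grp$start[o][-1] < grp$end[o][-nrow(grp)])) {
      stop(sprintf("overlapping segments for sample %s on %s",
                   grp$sample_id[1], grp$chrom[1]), call. = FALSE)
    }
  }
  invisible(segments)
}

#' Write segments as a SEG file (1-based inclusive)
#' @param segments segment data.frame (internal convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(ID = segments$sample_id, chrom = segments$chrom,
                    loc.start = format_coord(segments$start + 1),
                    loc.end = format_coord(segments$end),
                    seg.mean = segments$log2_ratio, stringsAsFactors = FALSE)
  write_tsv_with_meta(out, path)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Columns: `sample_id`, `purity`, plus any number of label columns
#' (e.g. driver mutation status) kept as-is.
#'
#' @param path TSV file with header.
#' @return data.frame with unique `sample_id` and `purity` in (0, 1].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "purity") %in% names(df))) {
    stop("sample sheet must have columns 'sample_id' and 'purity'", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  validate_sample_sheet(df)
  df
}

validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (any(!is.finite(sheet$purity)) || any(sheet$purity <= 0) || any(sheet$purity > 1)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  invisible(sheet)
}

#' Read somatic point mutations with allele read counts
#'
#' Expects a header and columns `sample_id`, `chrom`, `pos` (1-based on
#' disk, stored 0-based), `gene`, `ref_count`, `alt_count`, and optionally
#' `local_cn` (total copies at the locus; defaults to 2). Purity is joined in
#' from the sample sheet; every mutation's sample must appear there.
#'
#' @param path TSV file.
#' @param sample_sheet data.frame from [read_sample_sheet()].
#' @return data.frame with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `gene`, `ref_count`, `alt_count`, `local_cn`, `purity`.
#' @export
read_mutations <- function(path, sample_sheet) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "chrom", "pos", "gene", "ref_count", "alt_count")
  if (!all(need %in% names(df))) {
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (is.null(df$local_cn)) df$local_cn <- 2L
  df$pos <- as.numeric(df$pos) - 1  # 1-based -> 0-based
  missing <- setdiff(df$sample_id, sample_sheet$sample_id)
  if (length(missing)) {
    stop("mutation sample(s) absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$ref_count < 0) || any(df$alt_count < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  df$purity <- sample_sheet$purity[match(df$sample_id, sample_sheet$sample_id)]
  df[, c("sample_id", "chrom", "pos", "gene", "ref_count", "alt_count",
         "local_cn", "purity")]
}

#' Write mutations as TSV (1-based positions on disk)
#' @param mutations mutation data.frame (internal convention, 0-based `pos`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  out <- mutations[, c("sample_id", "chrom", "pos", "gene",
                       "ref_count", "alt_count", "local_cn")]
  out$pos <- format_coord(out$pos + 1)
  write_tsv_with_meta(out, path)
  invisible(path)
}

#' Read recurrent genomic regions from a BED file
#'
#' BED is 0-based half-open and kept as such. Regions are named by the
#' fourth column and must not overlap each other.
#'
#' @param path BED file (chrom, start, end, name).
#' @param genome a [genome_def()].
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions_bed <- function(path, genome) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4L) stop("region BED must have 4 columns (chrom,start,end,name)", call. = FALSE)
  regions <- data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
                        end = as.numeric(df[[3]]), name = as.character(df[[4]]),
                        stringsAsFactors = FALSE)
  check_chroms(regions$chrom, genome, "region")
  by_c <- split(regions, regions$chrom)
  for (grp in by_c) {
    o <- order(grp$start)
    if (nrow(grp) > 1 && any(grp$start[o][-1] < grp$end[o][-nrow(grp)])) {
      stop("recurrent regions must not overlap (", grp$chrom[1], ")", call. = FALSE)
    }
  }
  regions
}

#' Read an expression matrix (genes x samples) from TSV
#' @param path TSV with a header row of sample ids; first column gene ids.
#' @return numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  m
}

#' Read gene sets from a GMT file
#' @param path GMT file: per line, set name, description, then gene ids.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

# One TSV writer used everywhere: optional "# key: value" metadata header,
# then a header row and tab-separated body. Output is deterministic so
# reruns are byte-identical.
write_tsv_with_meta <- function(df, path, metadata = NULL) {
  body <- character()
  con <- textConnection("body", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  meta <- if (length(metadata)) {
    paste0("# ", names(metadata), ": ", unlist(metadata))
  } else character()
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' Each table is written as a TSV with a header (and an optional shared
#' metadata block of `# key: value` comment lines). Column order is taken
#' from the tables as given; reruns on identical inputs produce
#' byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param metadata optional named list written as comment lines atop each file.
#' @return manifest data.frame with columns `file`, `n_rows`.
#' @export
write_results <- function(tables, out_dir, metadata = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- paste0(names(tables), ".tsv")
  for (i in seq_along(tables)) {
    write_tsv_with_meta(tables[[i]], file.path(out_dir, files[i]), metadata)
  }
  data.frame(file = files,
             n_rows = vapply(tables, nrow, integer(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
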