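# Readers and writers for the plain-text formats the pipeline touches:
# BED3/BED4 tracks, UCSC chrom.sizes and cytoBand tables, SNP point lists,
# genetic maps, and the results TSV.  All readers validate coordinates
# against the layout and reject out-of-bounds input rather than clamping.

.read_lines_checked <- function(path) {
  if (!file.exists(path))
    .stop("io_error", sprintf("file not found: %s", path))
  readLines(path, warn = FALSE)
}

.is_skip_line <- function(x) {
  grepl("^(#|browser([[:space:]]|$)|track([[:space:]]|$))", x) |
    !nzchar(trimws(x))
}

.split_fields <- function(lines) strsplit(lines, "[\t ]+")

#' Read a BED file as a single segment track
#'
#' Accepts BED3 (chrom, start, end) or BED4 (with a label in column 4).
#' Comment, `browser` and `track` definition lines are skipped.  When
#' `label` is given, only rows carrying that label are kept; otherwise all
#' rows are read into one track.
#'
#' @param path Path to a BED file (0-based half-open coordinates).
#' @param layout A genome layout; out-of-bounds intervals are an error.
#' @param label Optional label filter; also used as the track label.
#' @return A `SegmentTrack`.
#' @seealso [read_segmentation()] to split a multi-state BED4 file into one
#'   track per state.
#' @export
read_bed <- function(path, layout, label = NULL) {
  parsed <- .parse_bed(path)
  df <- parsed
  if (!is.null(label)) {
    df <- df[!is.na(df$label) & df$label == label, , drop = FALSE]
  }
  lab <- if (!is.null(label)) label
         else if (nrow(df) > 0 && length(unique(stats::na.omit(df$label))) == 1L)
           unique(stats::na.omit(df$label))
         else basename(path)
  segment_track(df$chrom, df$start, df$end, layout, lab)
}

#' Read a multi-state segmentation BED4 file
#'
#' Splits a chromatin-state segmentation (one BED file, state label in
#' column 4) into one `SegmentTrack` per state label.
#'
#' @inheritParams read_bed
#' @return Named list of `SegmentTrack`s, one per state label.
#' @export
read_segmentation <- function(path, layout) {
  df <- .parse_bed(path)
  if (anyNA(df$label))
    .stop("parse_error",
          sprintf("%s: segmentation file needs a label in column 4", path))
  labs <- unique(df$label)
  out <- lapply(labs, function(l) {
    i <- df$label == l
    segment_track(df$chrom[i], df$start[i], df$end[i], layout, l)
  })
  stats::setNames(out, labs)
}

.parse_bed <- function(path) {
  lines <- .read_lines_checked(path)
  keep <- !.is_skip_line(lines)
  lineno <- which(keep)
  fields <- .split_fields(lines[keep])
  n <- length(fields)
  if (n == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0)))
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stop("parse_error", sprintf(
      "%s line %d: expected at least 3 columns (chrom, start, end)",
      path, lineno[nf < 3L][1L]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    .stop("parse_error", sprintf(
      "%s line %d: non-numeric start/end",
      path, lineno[is.na(start) | is.na(end)][1L]))
  if (any(bad <- end <= start))
    .stop("coordinate_error", sprintf(
      "%s line %d: end <= start", path, lineno[bad][1L]))
  label <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

#' Write a segment track as BED4
#'
#' Tab-separated, sorted, 0-based half-open, with the track label in
#' column 4.  `write_bed` followed by [read_bed()] is the identity on
#' canonical tracks.
#'
#' @param track A `SegmentTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  df <- track_intervals(track)
  lines <- if (nrow(df) == 0L) character(0) else
    sprintf("%s\t%s\t%s\t%s", df$chrom,
            format(df$start, scientific = FALSE, trim = TRUE),
            format(df$end, scientific = FALSE, trim = TRUE),
            track_label(track))
  tryCatch(writeLines(lines, path),
           error = function(e) .stop("io_error", conditionMessage(e)))
  invisible(path)
}

#' Read a UCSC chrom.sizes file as a genome layout
#'
#' @param path Two-column file: chromosome name, length in bp.
#' @return A genome layout (see [genome_layout()]).
#' @export
read_chrom_sizes <- function(path) {
  lines <- .read_lines_checked(path)
  fields <- .split_fields(lines[!.is_skip_line(lines)])
  if (any(lengths(fields) < 2L))
    .stop("parse_error", sprintf("%s: expected 'name<TAB>length' rows", path))
  genome_layout(vapply(fields, `[[`, "", 1L),
                as.numeric(vapply(fields, `[[`, "", 2L)))
}

#' Read a UCSC cytoBand table
#'
#' @param path Tab-separated file with columns chrom, start, end, band and
#'   optionally stain; the band name's leading letter (p/q) gives the arm.
#' @return A data.frame usable by [partition_arms()].
#' @export
read_cytoband <- function(path) {
  lines <- .read_lines_checked(path)
  fields <- .split_fields(lines[!.is_skip_line(lines)])
  if (any(lengths(fields) < 4L))
    .stop("parse_error",
          sprintf("%s: expected columns chrom, start, end, band", path))
  data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    band = vapply(fields, `[[`, "", 4L),
    stain = vapply(fields, function(f)
      if (length(f) >= 5L) f[[5L]] else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Read a SNP point list
#'
#' Tab-separated with a mandatory header line `id  chrom  pos0` or
#' `id  chrom  pos1`: the third column's name declares whether positions
#' are 0-based or 1-based.  There is no silent guessing — off-by-one
#' conventions are the dominant failure mode of point-in-interval tests.
#' 1-based positions are converted to the internal 0-based convention.
#'
#' @param path Path to the point list.
#' @param layout A genome layout.
#' @return A `PointTrack` (0-based positions).
#' @export
read_points <- function(path, layout) {
  lines <- .read_lines_checked(path)
  lines <- lines[!.is_skip_line(lines)]
  if (length(lines) == 0L)
    .stop("parse_error", sprintf("%s: missing header line", path))
  header <- .split_fields(lines[1L])[[1L]]
  if (length(header) < 3L || header[1L] != "id" || header[2L] != "chrom" ||
      !header[3L] %in% c("pos0", "pos1"))
    .stop("parse_error", sprintf(
      "%s: header must be 'id<TAB>chrom<TAB>pos0' or 'id<TAB>chrom<TAB>pos1' (declaring the base convention)",
      path))
  offset <- if (header[3L] == "pos1") 1 else 0
  fields <- .split_fields(lines[-1L])
  if (any(lengths(fields) < 3L))
    .stop("parse_error", sprintf("%s: expected 3 columns per point", path))
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(pos))
    .stop("parse_error", sprintf("%s: non-numeric position", path))
  point_track(vapply(fields, `[[`, "", 1L),
              vapply(fields, `[[`, "", 2L),
              pos - offset, layout)
}

#' Write a point track
#'
#' @param track A `PointTrack`.
#' @param path Output path; written 0-based with a `pos0` header.
#' @return `path`, invisibly.
#' @export
write_points <- function(track, path) {
  df <- track_points(track)
  lines <- c("id\tchrom\tpos0",
             sprintf("%s\t%s\t%s", df$id, df$chrom,
                     format(df$pos, scientific = FALSE, trim = TRUE)))
  tryCatch(writeLines(lines, path),
           error = function(e) .stop("io_error", conditionMessage(e)))
  invisible(path)
}

#' Read a genetic map
#'
#' Tab-separated with header `chrom  pos  cM`; positions are bp in the
#' internal 0-based system.  Per chromosome, positions must be strictly
#' increasing and map positions (cM) non-decreasing.
#'
#' @param path Path to the map file.
#' @param layout Optional genome layout; unknown chromosomes are an error.
#' @return A `genetic_map` object (see [genetic_map()]).
#' @export
read_genetic_map <- function(path, layout = NULL) {
  lines <- .read_lines_checked(path)
  lines <- lines[!.is_skip_line(lines)]
  if (length(lines) == 0L)
    .stop("parse_error", sprintf("%s: missing header line", path))
  header <- .split_fields(lines[1L])[[1L]]
  if (length(header) < 3L || !identical(header[1:3], c("chrom", "pos", "cM")))
    .stop("parse_error",
          sprintf("%s: header must be 'chrom<TAB>pos<TAB>cM'", path))
  fields <- .split_fields(lines[-1L])
  if (any(lengths(fields) < 3L))
    .stop("parse_error", sprintf("%s: expected 3 columns per map row", path))
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    cM = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    stringsAsFactors = FALSE)
  if (anyNA(df$pos) || anyNA(df$cM))
    .stop("parse_error", sprintf("%s: non-numeric pos/cM", path))
  genetic_map(df, layout = layout)
}

# -- results table ---------------------------------------------------------

.results_columns <- c("track_label", "bin_id", "observed_overlap",
                      "enrichment", "null_mean", "null_sd", "p_value",
                      "fdr_significant", "n_null_samples")

.validate_results <- function(table) {
  if (!all(.results_columns %in% names(table)))
    .stop("validation_error", sprintf(
      "results table needs columns: %s",
      paste(.results_columns, collapse = ", ")))
  if (nrow(table) > 0) {
    if (any(table$p_value <= 0 | table$p_value > 1, na.rm = TRUE))
      .stop("validation_error", "p_value must lie in (0, 1]")
    if (any(table$enrichment < 0, na.rm = TRUE))
      .stop("validation_error", "enrichment must be >= 0")
    if (anyDuplicated(paste(table$track_label, table$bin_id)))
      .stop("validation_error", "one row per (track, bin) required")
  }
  invisible(table)
}

# Decimal p-value formatting: 10 decimals with trailing zeros trimmed to a
# minimum of 5, so the value survives a round trip (the smallest reportable
# p is 1/n_samples) while matching the 5-decimal reporting convention.
.format_p <- function(p) {
  sub("(\\.\\d{5}\\d*?)0+$", "\\1", sprintf("%.10f", p))
}

#' Write a results table as TSV
#'
#' Fixed header and column order; p-values printed in decimal notation
#' with at least five decimals.
#'
#' @param table A results data.frame with columns `track_label`, `bin_id`,
#'   `observed_overlap`, `enrichment`, `null_mean`, `null_sd`, `p_value`,
#'   `fdr_significant`, `n_null_samples`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  .validate_results(table)
  out <- table[, .results_columns, drop = FALSE]
  out$p_value <- if (nrow(out) > 0) .format_p(out$p_value) else character(0)
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) .stop("io_error", conditionMessage(e)))
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A results data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    .stop("io_error", sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$fdr_significant <- as.logical(df$fdr_significant)
  .validate_results(df)
  df
}
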