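#' Construct a genome layout
#'
#' The coordinate universe for all tracks: an ordered set of named
#' chromosomes with integer lengths in base pairs.  All intervals and points
#' are validated against a layout, and all coordinates are 0-based,
#' half-open (BED convention).
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all > 0).
#' @return A [GenomeInfoDb::Seqinfo] object used as the layout.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms))
    .stop("validation_error", "chromosome names must be unique")
  lengths <- as.numeric(lengths)
  if (length(lengths) != length(chroms) || any(!is.finite(lengths)) ||
      any(lengths <= 0) || any(lengths != floor(lengths)))
    .stop("validation_error", "chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

.is_layout <- function(x) methods::is(x, "Seqinfo")

.layout_chroms <- function(layout) GenomeInfoDb::seqnames(layout)

.layout_lengths <- function(layout) {
  sl <- GenomeInfoDb::seqlengths(layout)
  stats::setNames(as.numeric(sl), names(sl))
}

.same_layout <- function(a, b) {
  identical(.layout_chroms(a), .layout_chroms(b)) &&
    identical(.layout_lengths(a), .layout_lengths(b))
}

.check_same_layout <- function(a, b) {
  if (!.same_layout(track_layout(a), track_layout(b)))
    .stop("configuration_error", "tracks are defined on different genome layouts")
}

# Validate 0-based half-open intervals against a layout; error names the
# first offending interval.
.check_bounds <- function(chrom, start, end, layout) {
  if (length(chrom) == 0L) return(invisible(NULL))
  known <- chrom %in% .layout_chroms(layout)
  if (!all(known))
    .stop("coordinate_error", sprintf(
      "unknown chromosome '%s' (not in layout)", chrom[!known][1L]))
  if (any(bad <- !is.finite(start) | !is.finite(end) | end <= start))
    .stop("coordinate_error", sprintf(
      "invalid interval %s:%s-%s (need 0 <= start < end)",
      chrom[bad][1L], format(start[bad][1L], scientific = FALSE),
      format(end[bad][1L], scientific = FALSE)))
  lens <- .layout_lengths(layout)[chrom]
  if (any(bad <- start < 0 | end > lens))
    .stop("coordinate_error", sprintf(
      "interval %s:%s-%s outside chromosome bounds [0, %s)",
      chrom[bad][1L], format(start[bad][1L], scientific = FALSE),
      format(end[bad][1L], scientific = FALSE),
      format(lens[bad][1L], scientific = FALSE)))
  invisible(NULL)
}

# Canonical interval data.frame: sorted by (layout chromosome order, start).
.order_runs_df <- function(df, layout) {
  o <- order(match(df$chrom, .layout_chroms(layout)), df$start)
  df <- df[o, c("chrom", "start", "end"), drop = FALSE]
  rownames(df) <- NULL
  df
}

# Merge an interval data.frame per chromosome (overlap + adjacency).
.merge_runs_df <- function(df, layout) {
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  pieces <- lapply(unique(df$chrom), function(cn) {
    i <- df$chrom == cn
    m <- .runs_merge(df$start[i], df$end[i])
    if (length(m$s) == 0L) return(NULL)
    data.frame(chrom = cn, start = m$s, end = m$e, stringsAsFactors = FALSE)
  })
  .order_runs_df(do.call(rbind, pieces), layout)
}

# Internal constructor: trusts df to be canonical (sorted, disjoint).
.new_segment_track <- function(df, layout, label) {
  structure(list(intervals = df, layout = layout,
                 label = as.character(label)),
            class = "SegmentTrack")
}

.empty_runs_df <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a segment track
#'
#' A set of genomic intervals carrying one label (a chromatin state such as
#' "AP" or a query set such as GWAS risk regions).  Overlapping and adjacent
#' input intervals are merged, so a track is canonical: sorted, pairwise
#' disjoint, and determined by its covered bases.
#'
#' @param chrom,start,end Parallel vectors of 0-based half-open intervals.
#' @param layout A genome layout from [genome_layout()].
#' @param label Single string naming the track.
#' @return A `SegmentTrack` object.
#' @examples
#' lo <- genome_layout("chr1", 1000)
#' segment_track("chr1", c(0, 5), c(10, 20), lo, "AP")
#' @export
segment_track <- function(chrom, start, end, layout, label = "track") {
  if (!.is_layout(layout))
    .stop("configuration_error", "layout must come from genome_layout()")
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  .check_bounds(chrom, start, end, layout)
  df <- .merge_runs_df(data.frame(chrom = chrom, start = start, end = end,
                                  stringsAsFactors = FALSE), layout)
  .new_segment_track(df, layout, label)
}

#' Merge intervals into a canonical disjoint set
#'
#' Sorts, merges overlapping intervals and coalesces adjacent ones (where
#' one interval's end equals the next one's start), preserving the covered
#' base set exactly.
#'
#' @param intervals A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param layout A genome layout; intervals outside it are an error.
#' @return A data.frame of sorted disjoint intervals.
#' @export
merge_intervals <- function(intervals, layout) {
  tr <- segment_track(intervals$chrom, intervals$start, intervals$end,
                      layout, "merged")
  track_intervals(tr)
}

#' @export
print.SegmentTrack <- function(x, ...) {
  cat(sprintf("SegmentTrack '%s': %d interval(s), %s bp covered on %d chromosome(s)\n",
              track_label(x), nrow(x$intervals),
              format(covered_bp(x), big.mark = ","),
              length(.layout_chroms(track_layout(x)))))
  invisible(x)
}

#' Track accessors
#'
#' @param track A `SegmentTrack` or `PointTrack`.
#' @return `track_label`: the label string; `track_layout`: the layout;
#'   `track_intervals`: a data.frame of 0-based half-open intervals;
#'   `covered_bp`: total covered bases.
#' @name track-accessors
NULL

#' @rdname track-accessors
#' @export
track_label <- function(track) track$label

#' @rdname track-accessors
#' @export
track_layout <- function(track) track$layout

#' @rdname track-accessors
#' @export
track_intervals <- function(track) track$intervals

#' @rdname track-accessors
#' @export
covered_bp <- function(track) {
  df <- track$intervals
  if (nrow(df) == 0L) return(0)
  sum(df$end - df$start)
}

#' Number of intervals in a track
#' @param track A `SegmentTrack`.
#' @return Integer count of intervals.
#' @export
n_intervals <- function(track) nrow(track$intervals)

#' Convert between segment tracks and GRanges
#'
#' `as_granges()` renders a track as a [GenomicRanges::GRanges] (1-based
#' closed coordinates, seqinfo from the layout) for interoperation with
#' the Bioconductor stack; `as_segment_track()` imports a GRanges whose
#' seqinfo carries chromosome lengths.
#'
#' @param track A `SegmentTrack`.
#' @return `as_granges()`: a `GRanges`; `as_segment_track()`: a
#'   `SegmentTrack`.
#' @export
as_granges <- function(track) {
  df <- track_intervals(track)
  .gr_from_runs(df$chrom, df$start, df$end, track_layout(track))
}

#' @rdname as_granges
#' @param gr A `GRanges` with seqlengths set.
#' @param label Track label for the imported track.
#' @export
as_segment_track <- function(gr, label = "track") {
  si <- GenomeInfoDb::seqinfo(gr)
  if (any(is.na(GenomeInfoDb::seqlengths(si))))
    .stop("configuration_error",
          "GRanges must carry seqlengths to define a layout")
  df <- .runs_from_gr(gr)
  segment_track(df$chrom, df$start, df$end, si, label)
}

# GRanges from 0-based half-open coordinates (shift to 1-based closed).
.gr_from_runs <- function(chrom, start, end, layout) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    seqinfo = layout)
}

# 0-based half-open data.frame from a GRanges.
.runs_from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE)
}

#' Construct a point track
#'
#' Genomic point positions (for example SNPs), 0-based.
#'
#' @param id Character vector of unique point identifiers (e.g. rsIDs).
#' @param chrom,pos Parallel chromosome names and 0-based positions.
#' @param layout A genome layout.
#' @return A `PointTrack` object.
#' @export
point_track <- function(id, chrom, pos, layout) {
  if (!.is_layout(layout))
    .stop("configuration_error", "layout must come from genome_layout()")
  id <- as.character(id)
  if (anyDuplicated(id))
    .stop("validation_error", "point ids must be unique")
  .check_bounds(chrom, pos, pos + 1, layout)
  o <- order(match(chrom, .layout_chroms(layout)), pos)
  structure(list(
    points = data.frame(id = id[o], chrom = as.character(chrom)[o],
                        pos = as.numeric(pos)[o], stringsAsFactors = FALSE),
    layout = layout), class = "PointTrack")
}

#' @export
print.PointTrack <- function(x, ...) {
  cat(sprintf("PointTrack: %d point(s) on %d chromosome(s)\n",
              nrow(x$points), length(unique(x$points$chrom))))
  invisible(x)
}

#' Track points as a data.frame
#' @param track A `PointTrack`.
#' @return data.frame with columns `id`, `chrom`, `pos` (0-based).
#' @export
track_points <- function(track) track$points

# Apply a per-chromosome boolean run operation between two canonical
# interval data.frames and return the canonical result.
.df_op <- function(a_df, b_df, layout, op) {
  chroms <- unique(c(a_df$chrom, b_df$chrom))
  pieces <- lapply(chroms, function(cn) {
    ia <- a_df$chrom == cn
    ib <- b_df$chrom == cn
    r <- .runs_op2(a_df$start[ia], a_df$end[ia],
                   b_df$start[ib], b_df$end[ib], op)
    if (length(r$s) == 0L) return(NULL)
    data.frame(chrom = cn, start = r$s, end = r$e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) .empty_runs_df() else .order_runs_df(out, layout)
}

#' Subtract one track from another
#'
#' Removes from `a` every base covered by `b` (used, for example, to strip
#' the bases two cell types' same-state tracks share when building
#' cell-type-specific case/control tracks).
#'
#' @param a,b `SegmentTrack`s on the same layout.
#' @return A `SegmentTrack` covering `covered(a)` minus `covered(b)`,
#'   labelled after `a`.
#' @export
subtract_track <- function(a, b) {
  .check_same_layout(a, b)
  df <- .df_op(track_intervals(a), track_intervals(b), track_layout(a),
               function(x, y) x & !y)
  .new_segment_track(df, track_layout(a), track_label(a))
}

#' Base-pair overlap between two tracks
#'
#' Total number of bases covered by both tracks; symmetric in its
#' arguments.  This is the observed statistic of the Monte Carlo overlap
#' tests.
#'
#' @param a,b `SegmentTrack`s on the same layout.
#' @return Overlap size in bp (numeric).
#' @export
overlap_bp <- function(a, b) {
  .check_same_layout(a, b)
  a_df <- track_intervals(a)
  b_df <- track_intervals(b)
  total <- 0
  for (cn in intersect(unique(a_df$chrom), unique(b_df$chrom))) {
    ia <- a_df$chrom == cn
    ib <- b_df$chrom == cn
    total <- total + .runs_overlap_bp(a_df$start[ia], a_df$end[ia],
                                      b_df$start[ib], b_df$end[ib])
  }
  total
}

#' Restrict a track to a set of bin intervals
#'
#' @param track A `SegmentTrack`.
#' @param bin A `SegmentTrack`, a data.frame of intervals, a `GRanges`, or
#'   one element of a [bin_partition()], giving the intervals to intersect
#'   with.
#' @return A `SegmentTrack` covering the intersection.
#' @export
restrict_track <- function(track, bin) {
  layout <- track_layout(track)
  bin_df <- .as_bin_df(bin, layout)
  df <- .df_op(track_intervals(track), bin_df, layout,
               function(x, y) x & y)
  .new_segment_track(df, layout, track_label(track))
}

#' Complement of a track within the genome (or a bin)
#'
#' @param track A `SegmentTrack`.
#' @param within Optional bin intervals; defaults to the whole layout.
#' @return A `SegmentTrack` covering every base of `within` not covered by
#'   `track`.
#' @export
complement_track <- function(track, within = NULL) {
  layout <- track_layout(track)
  universe <- if (is.null(within)) .layout_df(layout)
              else .as_bin_df(within, layout)
  df <- .df_op(universe, track_intervals(track), layout,
               function(x, y) x & !y)
  .new_segment_track(df, layout, paste0("not_", track_label(track)))
}

.layout_df <- function(layout) {
  lens <- .layout_lengths(layout)
  data.frame(chrom = names(lens), start = rep(0, length(lens)),
             end = unname(lens), stringsAsFactors = FALSE)
}

# Coerce a bin argument (data.frame, SegmentTrack, or GRanges) to a
# canonical interval data.frame on the given layout.
.as_bin_df <- function(bin, layout) {
  if (inherits(bin, "SegmentTrack")) {
    if (!.same_layout(track_layout(bin), layout))
      .stop("configuration_error", "bin is defined on a different genome layout")
    return(track_intervals(bin))
  }
  if (methods::is(bin, "GRanges")) bin <- .runs_from_gr(bin)
  if (is.data.frame(bin)) {
    .check_bounds(bin$chrom, bin$start, bin$end, layout)
    return(.merge_runs_df(bin[, c("chrom", "start", "end")], layout))
  }
  .stop("configuration_error", "cannot interpret bin argument")
}

#' Partition a genome into bins
#'
#' @param bins Named list; each element a data.frame of 0-based half-open
#'   intervals (`chrom`, `start`, `end`).  Bins must be pairwise disjoint.
#' @param layout A genome layout.
#' @return A `BinPartition`: a named list of bin interval sets.
#' @export
bin_partition <- function(bins, layout) {
  if (is.null(names(bins)) || anyDuplicated(names(bins)))
    .stop("validation_error", "bins must have unique names")
  dfs <- lapply(bins, .as_bin_df, layout = layout)
  all_df <- do.call(rbind, dfs)
  total_w <- sum(all_df$end - all_df$start)
  merged_w <- sum(vapply(unique(all_df$chrom), function(cn) {
    i <- all_df$chrom == cn
    .runs_covered(all_df$start[i], all_df$end[i])
  }, 0))
  if (merged_w < total_w)
    .stop("validation_error", "bins must be pairwise disjoint")
  structure(list(bins = dfs, layout = layout), class = "BinPartition")
}

#' @export
print.BinPartition <- function(x, ...) {
  cat(sprintf("BinPartition: %d bin(s): %s\n", length(x$bins),
              paste(utils::head(names(x$bins), 8), collapse = ", ")))
  invisible(x)
}

#' Bin ids of a partition
#' @param partition A `BinPartition`.
#' @return Character vector of bin ids.
#' @export
bin_ids <- function(partition) names(partition$bins)

#' Whole-genome bin partition
#'
#' A single bin spanning every chromosome, used for global-scale analyses.
#'
#' @param layout A genome layout.
#' @return A `BinPartition` with one bin named `"genome"`.
#' @export
whole_genome_bins <- function(layout) {
  bin_partition(list(genome = .layout_df(layout)), layout)
}

#' Partition a genome into chromosome arms
#'
#' Splits each chromosome at the centromere into a p bin and a q bin using
#' a UCSC-style cytoband table.  The p arm is `[0, boundary)` and the q arm
#' `[boundary, length)`, where the boundary is the start of the first
#' q band.  Acrocentric chromosomes with no annotated p bands yield a
#' single q bin covering the whole chromosome (and symmetrically for
#' q-less annotations).  Bins are labelled like `"chr1p"`.
#'
#' @param layout A genome layout.
#' @param cytobands A data.frame with columns `chrom`, `start`, `end`,
#'   `band` (band name whose leading letter, p or q, gives the arm), and
#'   optionally `stain`; see [read_cytoband()].
#' @return A `BinPartition` with one bin per represented arm.
#' @export
partition_arms <- function(layout, cytobands) {
  req <- c("chrom", "start", "end", "band")
  if (!all(req %in% names(cytobands)))
    .stop("configuration_error",
          "cytoband table needs columns chrom, start, end, band")
  lens <- .layout_lengths(layout)
  missing <- setdiff(names(lens), unique(cytobands$chrom))
  if (length(missing) > 0L)
    .stop("configuration_error", sprintf(
      "chromosome '%s' present in layout but absent from cytobands",
      missing[1L]))
  arm <- substr(cytobands$band, 1L, 1L)
  if (!all(arm %in% c("p", "q")))
    .stop("configuration_error", "band names must start with 'p' or 'q'")
  bins <- list()
  for (cn in names(lens)) {
    rows <- cytobands$chrom == cn
    has_p <- any(rows & arm == "p")
    has_q <- any(rows & arm == "q")
    if (has_p && has_q) {
      boundary <- min(cytobands$start[rows & arm == "q"])
      bins[[paste0(cn, "p")]] <- data.frame(chrom = cn, start = 0,
                                            end = boundary)
      bins[[paste0(cn, "q")]] <- data.frame(chrom = cn, start = boundary,
                                            end = lens[[cn]])
    } else {
      suffix <- if (has_q) "q" else "p"
      bins[[paste0(cn, suffix)]] <- data.frame(chrom = cn, start = 0,
                                               end = lens[[cn]])
    }
  }
  bin_partition(bins, layout)
}
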