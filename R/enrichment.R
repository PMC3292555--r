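#' Null model configuration
#'
#' Settings for the Monte Carlo permutation null: the number of null
#' samples (20,000 by default, giving a smallest reportable p-value of
#' 1/20,000 = 0.00005) and a master seed from which per-(track, bin)
#' substreams are derived deterministically.
#'
#' @param n_samples Number of Monte Carlo samples (>= 1).
#' @param seed Master seed (integer).
#' @return A `null_config` list.
#' @export
null_config <- function(n_samples = 20000, seed = 1) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    .stop("configuration_error", "n_samples must be a single value >= 1")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "null_config")
}

#' Fraction of a reference track covered by a query track
#'
#' The proportion of bases of `reference` (optionally restricted to bin
#' intervals) that are covered by `query`.
#'
#' @param reference,query `SegmentTrack`s on the same layout.
#' @param within Optional bin intervals to restrict both tracks to.
#' @return A fraction in `[0, 1]`.  An empty reference within the bin is an
#'   error (`undefined_proportion_error`); the caller decides exclusion.
#' @export
coverage_fraction <- function(reference, query, within = NULL) {
  .check_same_layout(reference, query)
  if (!is.null(within)) {
    reference <- restrict_track(reference, within)
    query <- restrict_track(query, within)
  }
  denom <- covered_bp(reference)
  if (denom == 0)
    .stop("undefined_proportion_error",
          "reference track covers no base within the bin")
  overlap_bp(reference, query) / denom
}

#' Enrichment ratio of a query track in a state track
#'
#' The proportion of state bases covered by the query, divided by the
#' proportion of non-state (complement) bases covered by the query.  A
#' value above 1 means the query preferentially covers the state.
#'
#' @param state The state track (e.g. one chromatin state).
#' @param query The query track (e.g. disease-associated regions).
#' @param within Optional bin intervals; the complement is taken within
#'   the bin (or the whole layout).
#' @return The enrichment ratio (>= 0).  Returns 0 when the query covers
#'   no state base; raises a `division_undefined_error` when the query
#'   covers no complement base (never a silent infinity).
#' @export
enrichment_ratio <- function(state, query, within = NULL) {
  .check_same_layout(state, query)
  comp <- complement_track(state, within = within)
  num <- coverage_fraction(state, query, within = within)
  den <- coverage_fraction(comp, query, within = within)
  if (den == 0) {
    if (num == 0) return(0)
    .stop("division_undefined_error",
          "query covers no base of the state's complement; ratio undefined")
  }
  num / den
}

# -- randomization null ----------------------------------------------------

# Decompose a track into per-region run sets for randomization.  `regions`
# is a data.frame(chrom, start, end) of disjoint contiguous regions.
# Errors if any segment crosses a region boundary or lies outside all
# regions ("restrict first").
.track_region_runs <- function(track, regions) {
  df <- track_intervals(track)
  out <- vector("list", nrow(regions))
  claimed <- 0
  for (i in seq_len(nrow(regions))) {
    on_chrom <- df$chrom == regions$chrom[i]
    inside <- on_chrom & df$start >= regions$start[i] & df$end <= regions$end[i]
    straddle <- on_chrom & !inside &
      df$start < regions$end[i] & df$end > regions$start[i]
    if (any(straddle))
      .stop("precondition_error", sprintf(
        "segment %s:%s-%s spans a bin boundary; restrict the track first",
        df$chrom[straddle][1L],
        format(df$start[straddle][1L], scientific = FALSE),
        format(df$end[straddle][1L], scientific = FALSE)))
    out[[i]] <- list(chrom = regions$chrom[i],
                     b0 = regions$start[i], b1 = regions$end[i],
                     s = df$start[inside], e = df$end[inside])
    claimed <- claimed + sum(inside)
  }
  if (claimed < nrow(df))
    .stop("precondition_error",
          "track has segments outside the bin; restrict the track first")
  out
}

.regions_df <- function(track, within) {
  layout <- track_layout(track)
  if (is.null(within)) return(.layout_df(layout))
  .as_bin_df(within, layout)
}

#' Randomize a track under the length-preserving null model
#'
#' Draws one sample from the null model in which segment locations vary
#' randomly while the empirical segment-length and inter-segment
#' (gap) length distributions are preserved *exactly*: within each
#' contiguous bin region the n segment lengths and the n + 1 gap lengths
#' (counting both flanks to the region boundaries) are each independently,
#' uniformly permuted and reassembled as gap, segment, gap, ..., gap.
#'
#' The returned track's intervals are sorted and disjoint but intentionally
#' not adjacency-coalesced, so the segment-length multiset of the input is
#' preserved for every input and seed (a permuted zero-length flank gap can
#' make two segments adjacent); covered-base statistics are unaffected.
#'
#' @param track A `SegmentTrack`, already restricted to `within`.
#' @param within Bin intervals confining the randomization; each contiguous
#'   interval is randomized independently.  Defaults to whole chromosomes.
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A `SegmentTrack` with the same label, covered bp, and
#'   segment-length multiset.
#' @export
randomize_track <- function(track, within = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- .regions_df(track, within)
  parts <- .track_region_runs(track, regions)
  pieces <- lapply(parts, function(p) {
    r <- .runs_randomize(p$s, p$e, p$b0, p$b1)
    if (length(r$s) == 0L) return(NULL)
    data.frame(chrom = p$chrom, start = r$s, end = r$e,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  layout <- track_layout(track)
  if (is.null(df) || nrow(df) == 0L) df <- .empty_runs_df()
  else df <- .order_runs_df(df, layout)
  .new_segment_track(df, layout, track_label(track))
}

#' Monte Carlo p-value
#'
#' One-sided p-value in the enrichment direction: the proportion of null
#' samples equal to or more extreme than (i.e. at least as large as) the
#' observed statistic, floored at 1/N so the smallest reportable p with
#' N = 20,000 samples is 0.00005.
#'
#' @param observed Observed statistic.
#' @param null_samples Numeric vector of statistics under the null (>= 1).
#' @return `max(k, 1) / N` where `k` is the number of samples `>= observed`.
#' @export
mc_pvalue <- function(observed, null_samples) {
  if (length(null_samples) == 0L)
    .stop("precondition_error", "need at least one null sample")
  if (!is.numeric(observed) || length(observed) != 1L || is.na(observed))
    .stop("precondition_error", "observed must be a single number")
  k <- sum(null_samples >= observed)
  max(k, 1) / length(null_samples)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up false discovery rate control at level `q`; flags are returned
#' in input order.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @param q FDR level (default 0.10).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  if (length(p_values) == 0L) return(logical(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    .stop("validation_error", "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

# One Monte Carlo overlap test over a set of contiguous regions.  `parts`
# comes from .track_region_runs on the state track; `query_runs` is a list
# parallel to `parts` with the fixed query runs restricted to each region.
# Observed and null statistics go through the same overlap code path.
.mc_overlap_test <- function(parts, query_runs, n_samples) {
  observed <- 0
  for (i in seq_along(parts))
    observed <- observed + .runs_overlap_bp(parts[[i]]$s, parts[[i]]$e,
                                            query_runs[[i]]$s,
                                            query_runs[[i]]$e)
  samples <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    tot <- 0
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p$s) == 0L || length(query_runs[[i]]$s) == 0L) next
      r <- .runs_randomize(p$s, p$e, p$b0, p$b1)
      tot <- tot + .runs_overlap_bp(r$s, r$e, query_runs[[i]]$s,
                                    query_runs[[i]]$e)
    }
    samples[k] <- tot
  }
  list(observed = observed, samples = samples)
}

.restrict_runs_to_region <- function(runs, chrom, b0, b1) {
  i <- runs$chrom == chrom & runs$start < b1 & runs$end > b0
  list(s = pmax(runs$start[i], b0), e = pmin(runs$end[i], b1))
}

.overlap_result <- function(track_label, bin_id, observed, enrichment,
                            samples, fdr_significant = NA) {
  structure(list(
    track_label = track_label, bin_id = bin_id, observed = observed,
    enrichment = enrichment, null_mean = mean(samples),
    null_sd = stats::sd(samples),
    p_value = mc_pvalue(observed, samples),
    n_null_samples = length(samples),
    fdr_significant = fdr_significant), class = "OverlapTestResult")
}

#' @export
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf(
    "Overlap test [%s, bin %s]\n  observed: %s bp  null: %.1f +/- %.1f bp\n  enrichment: %s  p = %s (N = %d)\n",
    x$track_label, x$bin_id, format(x$observed, big.mark = ","),
    x$null_mean, x$null_sd,
    if (is.na(x$enrichment)) "NA" else sprintf("%.3f", x$enrichment),
    .format_p(x$p_value), x$n_null_samples))
  invisible(x)
}

#' @export
as.data.frame.OverlapTestResult <- function(x, ...) {
  data.frame(track_label = x$track_label, bin_id = x$bin_id,
             observed_overlap = x$observed, enrichment = x$enrichment,
             null_mean = x$null_mean, null_sd = x$null_sd,
             p_value = x$p_value, fdr_significant = x$fdr_significant,
             n_null_samples = x$n_null_samples, stringsAsFactors = FALSE)
}

#' Combine overlap test results into a results table
#'
#' @param ... `OverlapTestResult` objects, results data.frames, or lists
#'   of either.
#' @return A validated results data.frame (see [write_results()]).
#' @export
results_table <- function(...) {
  items <- list(...)
  flat <- list()
  for (it in items) {
    if (inherits(it, "OverlapTestResult") || is.data.frame(it))
      flat <- c(flat, list(it))
    else flat <- c(flat, it)
  }
  rows <- lapply(flat, function(x)
    if (is.data.frame(x)) x else as.data.frame(x))
  tab <- do.call(rbind, rows)
  .validate_results(tab)
}

#' Global overlap test between a state track and a fixed query track
#'
#' Tests whether the base-pair overlap between a chromatin-state track and
#' a query-region track exceeds chance expectation.  The query is held
#' fixed; the state track is randomized independently within each
#' chromosome under the length-preserving null ([randomize_track()]).  The
#' p-value is the one-sided Monte Carlo p ([mc_pvalue()]); the enrichment
#' ratio is computed over the whole layout ([enrichment_ratio()]).
#'
#' @param state,query `SegmentTrack`s on the same layout.
#' @param config A [null_config()].
#' @return An `OverlapTestResult`.
#' @export
test_overlap_global <- function(state, query, config = null_config()) {
  .check_same_layout(state, query)
  regions <- .regions_df(state, NULL)
  parts <- .track_region_runs(state, regions)
  qdf <- track_intervals(query)
  query_runs <- lapply(seq_len(nrow(regions)), function(i)
    .restrict_runs_to_region(qdf, regions$chrom[i], regions$start[i],
                             regions$end[i]))
  enr <- tryCatch(enrichment_ratio(state, query),
                  undefined_proportion_error = function(e) NA_real_,
                  division_undefined_error = function(e) NA_real_)
  set.seed(derive_seed(config$seed,
                       paste0("global:", track_label(state))))
  mc <- .mc_overlap_test(parts, query_runs, config$n_samples)
  .overlap_result(track_label(state), "genome", mc$observed, enr,
                  mc$samples)
}

#' Local (binned) overlap test with FDR control
#'
#' Runs the overlap test of [test_overlap_global()] separately within each
#' bin of a partition (typically chromosome arms from [partition_arms()]),
#' with the randomization confined to the bin.  Bins in which the query
#' covers no base are excluded from testing and from the FDR adjustment
#' (they are listed in the `excluded_bins` attribute), mirroring the
#' exclusion of arms that contain no query regions.  Benjamini-Hochberg
#' flags at level `fdr_q` are set across the retained bins of this state
#' track.
#'
#' @param state,query `SegmentTrack`s on the same layout.
#' @param bins A `BinPartition`.
#' @param config A [null_config()].
#' @param fdr_q FDR level across bins (default 0.10).
#' @return A results data.frame, one row per retained bin, with attribute
#'   `excluded_bins`.
#' @export
test_overlap_local <- function(state, query, bins, config = null_config(),
                               fdr_q = 0.10) {
  .check_same_layout(state, query)
  if (!inherits(bins, "BinPartition"))
    .stop("configuration_error", "bins must be a BinPartition")
  results <- list()
  excluded <- character(0)
  for (bid in bin_ids(bins)) {
    bin_df <- bins$bins[[bid]]
    query_b <- restrict_track(query, bin_df)
    if (covered_bp(query_b) == 0) {
      excluded <- c(excluded, bid)
      next
    }
    state_b <- restrict_track(state, bin_df)
    regions <- bin_df
    parts <- .track_region_runs(state_b, regions)
    qdf <- track_intervals(query_b)
    query_runs <- lapply(seq_len(nrow(regions)), function(i)
      .restrict_runs_to_region(qdf, regions$chrom[i], regions$start[i],
                               regions$end[i]))
    enr <- tryCatch(
      enrichment_ratio(state, query, within = bin_df),
      undefined_proportion_error = function(e) NA_real_,
      division_undefined_error = function(e) NA_real_)
    set.seed(derive_seed(config$seed,
                         paste0("local:", track_label(state), ":", bid)))
    mc <- .mc_overlap_test(parts, query_runs, config$n_samples)
    results[[bid]] <- .overlap_result(track_label(state), bid, mc$observed,
                                      enr, mc$samples)
  }
  if (length(results) == 0L) {
    tab <- results_table(list(data.frame(
      track_label = character(0), bin_id = character(0),
      observed_overlap = numeric(0), enrichment = numeric(0),
      null_mean = numeric(0), null_sd = numeric(0), p_value = numeric(0),
      fdr_significant = logical(0), n_null_samples = integer(0))))
  } else {
    tab <- results_table(results)
    tab$fdr_significant <- bh_fdr(tab$p_value, q = fdr_q)
  }
  attr(tab, "excluded_bins") <- excluded
  tab
}
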