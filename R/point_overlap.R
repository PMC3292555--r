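#' Count points lying inside a state track
#'
#' A 0-based point position `p` lies inside an interval `[start, end)` iff
#' `start <= p < end` (a point at a state interval's first base counts; a
#' point at its end coordinate does not).
#'
#' @param points A `PointTrack`.
#' @param state A `SegmentTrack` on the same layout.
#' @return Integer count of points inside the state.
#' @export
count_points_in_track <- function(points, state) {
  if (!.same_layout(track_layout(points), track_layout(state)))
    .stop("configuration_error",
          "points and state are on different genome layouts")
  pdf <- track_points(points)
  sdf <- track_intervals(state)
  total <- 0L
  for (cn in unique(pdf$chrom)) {
    i <- sdf$chrom == cn
    total <- total + .runs_count_points(pdf$pos[pdf$chrom == cn],
                                        sdf$start[i], sdf$end[i])
  }
  as.integer(total)
}

#' Percentage of points in a state
#'
#' @param n_in_state,n_points Counts with `n_points > 0`.
#' @return `100 * n_in_state / n_points`, rounded to 2 decimals.
#' @examples
#' point_percentage(30, 452)  # 6.64
#' @export
point_percentage <- function(n_in_state, n_points) {
  if (!is.numeric(n_points) || n_points <= 0)
    .stop("precondition_error", "n_points must be > 0")
  round(100 * n_in_state / n_points, 2)
}

#' Point-in-state Monte Carlo test
#'
#' Tests whether points (e.g. trait-associated SNPs) fall inside a
#' chromatin state more than expected by chance.  Following the same null
#' as the region-overlap tests, the *state track* is randomized under the
#' length-preserving null while the points stay fixed.  Enrichment is the
#' observed in-state count divided by the mean null count.
#'
#' @param points A `PointTrack` (held fixed).
#' @param state A `SegmentTrack` (randomized per chromosome).
#' @param config A [null_config()].
#' @return A `PointOverlapResult` with fields `n_points`, `n_in_state`,
#'   `percentage`, `enrichment`, `p_value`, `null_mean`, `null_sd`,
#'   `n_null_samples`.
#' @export
point_overlap_test <- function(points, state, config = null_config()) {
  if (!.same_layout(track_layout(points), track_layout(state)))
    .stop("configuration_error",
          "points and state are on different genome layouts")
  pdf <- track_points(points)
  n_points <- nrow(pdf)
  if (n_points == 0L)
    .stop("precondition_error", "point track is empty")
  regions <- .regions_df(state, NULL)
  parts <- .track_region_runs(state, regions)
  pos_by_region <- lapply(seq_len(nrow(regions)), function(i) {
    p <- pdf$pos[pdf$chrom == regions$chrom[i]]
    p[p >= regions$start[i] & p < regions$end[i]]
  })
  observed <- 0L
  for (i in seq_along(parts))
    observed <- observed + .runs_count_points(pos_by_region[[i]],
                                              parts[[i]]$s, parts[[i]]$e)
  set.seed(derive_seed(config$seed, paste0("points:", track_label(state))))
  samples <- vapply(seq_len(config$n_samples), function(k) {
    tot <- 0L
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p$s) == 0L || length(pos_by_region[[i]]) == 0L) next
      r <- .runs_randomize(p$s, p$e, p$b0, p$b1)
      tot <- tot + .runs_count_points(pos_by_region[[i]], r$s, r$e)
    }
    as.integer(tot)
  }, 0L)
  null_mean <- mean(samples)
  if (null_mean == 0)
    .stop("undefined_ratio_error",
          "null mean in-state count is zero; enrichment undefined")
  structure(list(
    track_label = track_label(state),
    n_points = n_points, n_in_state = as.integer(observed),
    percentage = point_percentage(observed, n_points),
    enrichment = observed / null_mean,
    p_value = mc_pvalue(observed, samples),
    null_mean = null_mean, null_sd = stats::sd(samples),
    n_null_samples = length(samples)), class = "PointOverlapResult")
}

#' @export
print.PointOverlapResult <- function(x, ...) {
  cat(sprintf(
    "Point-in-state test [%s]\n  %d / %d points in state (%.2f%%)  null mean %.1f\n  enrichment: %.3f  p = %s (N = %d)\n",
    x$track_label, x$n_in_state, x$n_points, x$percentage, x$null_mean,
    x$enrichment, .format_p(x$p_value), x$n_null_samples))
  invisible(x)
}

#' @export
as.data.frame.PointOverlapResult <- function(x, ...) {
  data.frame(track_label = x$track_label, bin_id = "genome",
             observed_overlap = x$n_in_state, enrichment = x$enrichment,
             null_mean = x$null_mean, null_sd = x$null_sd,
             p_value = x$p_value, fdr_significant = NA,
             n_null_samples = x$n_null_samples, stringsAsFactors = FALSE)
}
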