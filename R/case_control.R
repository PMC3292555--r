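#' Labeled case/control interval set
#'
#' Disjoint genomic intervals each carrying a `case` or `control` label,
#' typically the cell-type-specific remainders of two cell types'
#' same-state chromatin tracks (see [build_differential_tracks()]).
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `label` (`"case"` or `"control"`).
#' @param layout A genome layout.
#' @return A `LabeledIntervalSet`.
#' @export
labeled_intervals <- function(intervals, layout) {
  req <- c("chrom", "start", "end", "label")
  if (!all(req %in% names(intervals)))
    .stop("validation_error",
          "intervals need columns chrom, start, end, label")
  if (!all(intervals$label %in% c("case", "control")))
    .stop("validation_error", "labels must be 'case' or 'control'")
  .check_bounds(intervals$chrom, intervals$start, intervals$end, layout)
  o <- order(match(intervals$chrom, .layout_chroms(layout)), intervals$start)
  df <- intervals[o, req, drop = FALSE]
  rownames(df) <- NULL
  # pairwise disjoint across both labels
  for (cn in unique(df$chrom)) {
    i <- df$chrom == cn
    s <- df$start[i]; e <- df$end[i]
    if (any(s[-1L] < e[-length(e)]))
      .stop("validation_error", "labeled intervals must be pairwise disjoint")
  }
  structure(list(intervals = df, layout = layout),
            class = "LabeledIntervalSet")
}

#' @export
print.LabeledIntervalSet <- function(x, ...) {
  n <- table(factor(x$intervals$label, levels = c("case", "control")))
  cat(sprintf("LabeledIntervalSet: %d case, %d control interval(s)\n",
              n[["case"]], n[["control"]]))
  invisible(x)
}

#' Build cell-type-specific case/control tracks for one chromatin state
#'
#' Removes every base shared between the two cell types' same-state tracks
#' and labels the remaining intervals `case` (first cell type) or
#' `control` (second).  Shared bases appear in neither class.
#'
#' @param case_state State track of the case cell type (e.g. B cells).
#' @param control_state Same-state track of the control cell type.
#' @return A `LabeledIntervalSet`.
#' @export
build_differential_tracks <- function(case_state, control_state) {
  .check_same_layout(case_state, control_state)
  case_only <- track_intervals(subtract_track(case_state, control_state))
  ctrl_only <- track_intervals(subtract_track(control_state, case_state))
  case_only$label <- rep("case", nrow(case_only))
  ctrl_only$label <- rep("control", nrow(ctrl_only))
  labeled_intervals(rbind(case_only, ctrl_only), track_layout(case_state))
}

# Per-interval overlap bp with a query track, in interval order.
.interval_query_overlap <- function(labeled, query) {
  df <- labeled$intervals
  if (nrow(df) == 0L) return(numeric(0))
  qdf <- track_intervals(query)
  vapply(seq_len(nrow(df)), function(i) {
    q <- .restrict_runs_to_region(qdf, df$chrom[i], df$start[i], df$end[i])
    sum(q$e - q$s)
  }, 0)
}

#' Fold enrichment difference between case and control intervals
#'
#' The proportion of case-interval bases overlapped by the query, divided
#' by the same proportion for control intervals.
#'
#' @param labeled A `LabeledIntervalSet`.
#' @param query A query `SegmentTrack` on the same layout.
#' @return The fold difference (ratio of overlap proportions).  An empty
#'   label class is an `undefined_ratio_error`; zero control overlap with
#'   nonzero case overlap is a `division_undefined_error`.
#' @export
fold_enrichment_difference <- function(labeled, query) {
  if (!.same_layout(labeled$layout, track_layout(query)))
    .stop("configuration_error", "query is on a different genome layout")
  df <- labeled$intervals
  is_case <- df$label == "case"
  case_total <- sum(df$end[is_case] - df$start[is_case])
  ctrl_total <- sum(df$end[!is_case] - df$start[!is_case])
  if (case_total == 0 || ctrl_total == 0)
    .stop("undefined_ratio_error",
          "both label classes need positive total bp")
  ov <- .interval_query_overlap(labeled, query)
  case_prop <- sum(ov[is_case]) / case_total
  ctrl_prop <- sum(ov[!is_case]) / ctrl_total
  if (ctrl_prop == 0) {
    if (case_prop == 0) return(0)
    .stop("division_undefined_error",
          "control intervals have zero query overlap; fold difference undefined")
  }
  case_prop / ctrl_prop
}

#' Case-control label permutation test
#'
#' Tests whether case-labeled intervals overlap the query more than
#' expected if case/control labels were exchangeable.  The observed
#' statistic is the base-pair overlap between case intervals and the
#' query; each Monte Carlo sample uniformly permutes the label sequence
#' over the fixed interval positions (preserving the number of case
#' labels) and recomputes it.  Interval positions never move, so
#' interval-length heterogeneity is part of the null.
#'
#' @param labeled A `LabeledIntervalSet` with both labels present and at
#'   least two intervals.
#' @param query A query `SegmentTrack`.
#' @param config A [null_config()].
#' @return An `OverlapTestResult` whose `enrichment` field is the
#'   [fold_enrichment_difference()] (NA if undefined).
#' @export
case_control_test <- function(labeled, query, config = null_config()) {
  df <- labeled$intervals
  n_case <- sum(df$label == "case")
  if (nrow(df) < 2L || n_case == 0L || n_case == nrow(df))
    .stop("precondition_error",
          "need >= 2 intervals with both labels present")
  ov <- .interval_query_overlap(labeled, query)
  observed <- sum(ov[df$label == "case"])
  fold <- tryCatch(fold_enrichment_difference(labeled, query),
                   division_undefined_error = function(e) NA_real_)
  set.seed(derive_seed(config$seed, "case_control"))
  n <- nrow(df)
  samples <- vapply(seq_len(config$n_samples), function(k)
    sum(ov[sample.int(n, n_case)]), 0)
  .overlap_result("case_vs_control", "genome", observed, fold, samples)
}
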