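#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic-data generator: a genome
#' layout, chromatin states with geometric segment-length distributions
#' and target genome fractions, a query-region generator with a
#' controllable enrichment factor toward one target state, and a point
#' generator with a controllable in-state probability multiplier.
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param states data.frame with columns `label`, `mean_len` (mean segment
#'   length, bp, > 0) and `fraction` (target genome fraction; fractions
#'   must sum to <= 1).
#' @param query list(`n_regions`, `mean_width` bp, `enrichment_factor`
#'   >= 0, `target` state label).
#' @param points list(`n_points`, `multiplier` >= 0, `target` state label).
#' @param seed Master seed for the generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chromosomes,
                       states = data.frame(label = "S", mean_len = 10000,
                                           fraction = 0.2),
                       query = list(n_regions = 100, mean_width = 500,
                                    enrichment_factor = 1, target = "S"),
                       points = list(n_points = 500, multiplier = 1,
                                     target = "S"),
                       seed = 1) {
  layout <- genome_layout(names(chromosomes), chromosomes)
  if (!all(c("label", "mean_len", "fraction") %in% names(states)))
    .stop("configuration_error",
          "states need columns label, mean_len, fraction")
  if (any(states$mean_len <= 0))
    .stop("configuration_error", "state mean lengths must be > 0")
  if (any(states$fraction < 0) || sum(states$fraction) > 1)
    .stop("configuration_error",
          "state fractions must be >= 0 and sum to <= 1")
  if (!is.null(query$enrichment_factor) && query$enrichment_factor < 0)
    .stop("configuration_error", "enrichment_factor must be >= 0")
  if (!is.null(points$multiplier) && points$multiplier < 0)
    .stop("configuration_error", "multiplier must be >= 0")
  structure(list(layout = layout, states = states, query = query,
                 points = points, seed = as.integer(seed)),
            class = "sim_config")
}

# Geometric draw with mean m and support >= 1 (segment lengths).
.rgeom1 <- function(n, m) stats::rgeom(n, prob = 1 / max(m, 1)) + 1

# Geometric draw with mean m and support >= 0 (gap lengths).
.rgeom0 <- function(n, m) stats::rgeom(n, prob = 1 / (1 + max(m, 0)))

#' Simulate chromatin-state tracks
#'
#' Per chromosome, alternates background gaps and state segments: gap
#' lengths are geometric with a mean chosen so each state's realized
#' genome fraction matches its target; each segment's state is drawn with
#' probability proportional to `fraction / mean_len` and its length is
#' geometric around the state's `mean_len`.  The resulting per-state
#' tracks are disjoint.
#'
#' @param config A [sim_config()].
#' @return Named list of `SegmentTrack`s, one per state label (empty for
#'   fraction-0 states), with the layout attached as attribute `layout`.
#' @export
simulate_chromatin <- function(config) {
  set.seed(derive_seed(config$seed, "chromatin"))
  st <- config$states
  layout <- config$layout
  f_tot <- sum(st$fraction)
  z <- sum(st$fraction / st$mean_len)
  pick <- if (z > 0) (st$fraction / st$mean_len) / z else
    rep(0, nrow(st))
  mean_gap <- if (z > 0) (1 - f_tot) / z else 1
  lens <- .layout_lengths(layout)
  per_state <- stats::setNames(
    replicate(nrow(st), list(chrom = character(0), s = numeric(0),
                             e = numeric(0)), simplify = FALSE),
    st$label)
  for (cn in names(lens)) {
    if (z == 0) break
    pos <- 0
    len <- lens[[cn]]
    while (pos < len) {
      pos <- pos + .rgeom0(1L, mean_gap)
      if (pos >= len) break
      which_state <- sample.int(nrow(st), 1L, prob = pick)
      seg <- .rgeom1(1L, st$mean_len[which_state])
      e <- min(pos + seg, len)
      lab <- st$label[which_state]
      per_state[[lab]]$chrom <- c(per_state[[lab]]$chrom, cn)
      per_state[[lab]]$s <- c(per_state[[lab]]$s, pos)
      per_state[[lab]]$e <- c(per_state[[lab]]$e, e)
      pos <- e
    }
  }
  out <- lapply(st$label, function(lab) {
    p <- per_state[[lab]]
    segment_track(p$chrom, p$s, p$e, layout, lab)
  })
  names(out) <- st$label
  attr(out, "layout") <- layout
  out
}

# Sample n positions uniformly over the covered bases of an interval set.
.sample_bases <- function(df, n) {
  widths <- df$end - df$start
  total <- sum(widths)
  if (total <= 0 || n == 0L)
    return(data.frame(chrom = character(0), pos = numeric(0)))
  u <- floor(stats::runif(n) * total)
  cw <- cumsum(widths)
  idx <- findInterval(u, c(0, cw[-length(cw)] )) # 1-based interval index
  idx <- pmin(pmax(idx, 1L), nrow(df))
  offset <- u - c(0, cw)[idx]
  data.frame(chrom = df$chrom[idx], pos = df$start[idx] + offset,
             stringsAsFactors = FALSE)
}

.target_track <- function(states, target) {
  if (!target %in% names(states))
    .stop("configuration_error",
          sprintf("target state '%s' not among simulated states", target))
  states[[target]]
}

#' Simulate query regions with a planted enrichment
#'
#' Region start positions come from a two-component mixture: with weight
#' `ef * c / (ef * c + (1 - c))` — where `ef` is the enrichment factor and
#' `c` the target state's realized coverage fraction — the start is
#' uniform over target-state bases, otherwise uniform over non-state
#' bases.  The in-state versus out-of-state start density ratio is then
#' exactly `ef`, and `ef = 1` reduces to uniform placement over the
#' genome.  Widths are geometric around `mean_width`.
#'
#' @param config A [sim_config()].
#' @param states Output of [simulate_chromatin()].
#' @return A `SegmentTrack` of (merged) query regions labelled `"query"`.
#' @export
simulate_query <- function(config, states) {
  set.seed(derive_seed(config$seed, "query"))
  q <- config$query
  layout <- config$layout
  target <- .target_track(states, q$target)
  genome_bp <- sum(.layout_lengths(layout))
  c_frac <- covered_bp(target) / genome_bp
  ef <- q$enrichment_factor
  w_in <- if (c_frac <= 0) 0 else ef * c_frac / (ef * c_frac + (1 - c_frac))
  in_state <- stats::runif(q$n_regions) < w_in
  tdf <- track_intervals(target)
  cdf <- track_intervals(complement_track(target))
  starts_in <- .sample_bases(tdf, sum(in_state))
  starts_out <- .sample_bases(cdf, sum(!in_state))
  starts <- rbind(starts_in, starts_out)
  widths <- .rgeom1(nrow(starts), q$mean_width)
  lens <- .layout_lengths(layout)
  end <- pmin(starts$pos + widths, lens[starts$chrom])
  segment_track(starts$chrom, starts$pos, end, layout, "query")
}

#' Simulate a point track with a planted in-state probability
#'
#' Each point lands inside the target state with probability
#' `multiplier * c` (where `c` is the state's coverage fraction), uniform
#' over state bases, and otherwise uniform over non-state bases.
#' `multiplier * c > 1` is a configuration error.
#'
#' @param config A [sim_config()].
#' @param states Output of [simulate_chromatin()].
#' @return A `PointTrack` with ids `snp_1 ... snp_n`.
#' @export
simulate_points <- function(config, states) {
  set.seed(derive_seed(config$seed, "points"))
  p <- config$points
  layout <- config$layout
  target <- .target_track(states, p$target)
  genome_bp <- sum(.layout_lengths(layout))
  c_frac <- covered_bp(target) / genome_bp
  p_in <- p$multiplier * c_frac
  if (p_in > 1)
    .stop("configuration_error",
          "multiplier x coverage fraction exceeds 1")
  in_state <- stats::runif(p$n_points) < p_in
  tdf <- track_intervals(target)
  cdf <- track_intervals(complement_track(target))
  pts_in <- .sample_bases(tdf, sum(in_state))
  pts_out <- .sample_bases(cdf, sum(!in_state))
  pts <- rbind(pts_in, pts_out)
  point_track(sprintf("snp_%d", seq_len(nrow(pts))), pts$chrom, pts$pos,
              layout)
}
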