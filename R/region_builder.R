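#' Construct a genetic map
#'
#' A per-chromosome piecewise-linear mapping between physical position
#' (bp, 0-based) and genetic map position (cM).  Per chromosome, at least
#' two knots are required, positions must be strictly increasing, and cM
#' values non-decreasing (flat stretches are recombination plateaus).
#'
#' @param map data.frame with columns `chrom`, `pos` (bp), `cM`.
#' @param layout Optional genome layout; unknown chromosomes are an error.
#' @return A `genetic_map` object.
#' @export
genetic_map <- function(map, layout = NULL) {
  req <- c("chrom", "pos", "cM")
  if (!all(req %in% names(map)))
    .stop("validation_error", "map needs columns chrom, pos, cM")
  if (!is.null(layout)) {
    unknown <- setdiff(unique(map$chrom), .layout_chroms(layout))
    if (length(unknown) > 0L)
      .stop("coordinate_error", sprintf(
        "unknown chromosome '%s' in genetic map", unknown[1L]))
  }
  map <- map[order(map$chrom, map$pos), req, drop = FALSE]
  for (cn in unique(map$chrom)) {
    i <- map$chrom == cn
    if (sum(i) < 2L)
      .stop("validation_error", sprintf(
        "genetic map needs >= 2 points on chromosome %s", cn))
    if (any(diff(map$pos[i]) <= 0))
      .stop("validation_error", sprintf(
        "map positions must be strictly increasing on chromosome %s", cn))
    if (any(diff(map$cM[i]) < 0))
      .stop("validation_error", sprintf(
        "cM values must be non-decreasing on chromosome %s", cn))
  }
  rownames(map) <- NULL
  structure(list(map = map), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d knot(s) on %d chromosome(s)\n",
              nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

.map_knots <- function(map, chrom) {
  i <- map$map$chrom == chrom
  if (!any(i))
    .stop("coordinate_error",
          sprintf("no genetic map for chromosome %s", chrom))
  list(pos = map$map$pos[i], cM = map$map$cM[i])
}

#' Interpolate genetic map position
#'
#' Linear interpolation of the cM coordinate at a physical position;
#' exact at map knots.  Positions outside the map's physical domain raise
#' an `extrapolation_error` — there is no silent extrapolation.
#'
#' @param pos Physical position(s) in bp (0-based).
#' @param map A [genetic_map()].
#' @param chrom Chromosome name.
#' @return cM value(s).
#' @export
interpolate_cm <- function(pos, map, chrom) {
  k <- .map_knots(map, chrom)
  if (any(pos < k$pos[1L] | pos > k$pos[length(k$pos)]))
    .stop("extrapolation_error", sprintf(
      "position outside genetic map domain [%s, %s] on %s",
      format(k$pos[1L], scientific = FALSE),
      format(k$pos[length(k$pos)], scientific = FALSE), chrom))
  stats::approx(k$pos, k$cM, xout = pos, ties = "ordered")$y
}

# Physical position attaining a target cM value.  side = "left" gives the
# leftmost such position, side = "right" the rightmost (within a
# zero-recombination plateau the outermost extent is taken).  Targets
# beyond the map's cM range clamp to the map's endpoint positions only
# when the map reaches the chromosome boundary there; otherwise the map
# domain is too short and an extrapolation error is raised.
.inverse_cm <- function(target, knots, side, chrom_len) {
  pos <- knots$pos; cm <- knots$cM
  n <- length(pos)
  if (target <= cm[1L]) {
    if (target < cm[1L] && pos[1L] > 0)
      .stop("extrapolation_error",
            "genetic map domain too short below the target window")
    i <- which(cm == cm[1L])
    return(if (side == "left") pos[1L] else pos[max(i)])
  }
  if (target >= cm[n]) {
    if (target > cm[n] && pos[n] < chrom_len)
      .stop("extrapolation_error",
            "genetic map domain too short above the target window")
    i <- which(cm == cm[n])
    return(if (side == "right") pos[n] else pos[min(i)])
  }
  hits <- which(cm == target)
  if (length(hits) > 0L)
    return(if (side == "left") pos[min(hits)] else pos[max(hits)])
  j <- findInterval(target, cm)        # cm[j] < target < cm[j+1]
  frac <- (target - cm[j]) / (cm[j + 1L] - cm[j])
  raw <- pos[j] + frac * (pos[j + 1L] - pos[j])
  if (side == "left") floor(raw) else ceiling(raw)
}

#' Build a fixed genetic-width query region around a lead SNP
#'
#' Constructs the genomic interval of `width_cM` centimorgans centred (in
#' genetic coordinates) on the lead SNP: the window
#' `[c - width/2, c + width/2]` in cM, where `c` is the lead's
#' interpolated map position, inverted back to physical coordinates.
#' Within zero-recombination plateaus the outermost physical positions
#' are taken (maximal region); boundaries beyond the chromosome ends are
#' clipped, never wrapped.
#'
#' @param lead_pos Lead SNP position in bp (0-based).
#' @param map A [genetic_map()].
#' @param chrom Chromosome name.
#' @param layout A genome layout (for chromosome-bound clipping).
#' @param width_cM Genetic width of the region (default 0.25 cM).
#' @return data.frame with one row: `chrom`, `start`, `end` (0-based
#'   half-open); always contains the lead position.
#' @export
build_region <- function(lead_pos, map, chrom, layout, width_cM = 0.25) {
  if (width_cM < 0)
    .stop("configuration_error", "width_cM must be >= 0")
  chrom_len <- .layout_lengths(layout)[[chrom]]
  k <- .map_knots(map, chrom)
  centre <- interpolate_cm(lead_pos, map, chrom)
  left <- .inverse_cm(centre - width_cM / 2, k, "left", chrom_len)
  right <- .inverse_cm(centre + width_cM / 2, k, "right", chrom_len)
  start <- max(0, left)
  end <- min(chrom_len, max(right, lead_pos + 1))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Build a query-region track around a set of lead SNPs
#'
#' Applies [build_region()] to each point of a lead-SNP track and merges
#' the resulting windows (overlapping regions from nearby leads coalesce)
#' into a canonical query track.
#'
#' @param leads A `PointTrack` of lead SNPs.
#' @param map A [genetic_map()].
#' @param width_cM Genetic width per region (default 0.25 cM).
#' @param label Track label for the result (default `"query_regions"`).
#' @return A `SegmentTrack` of merged query regions.
#' @export
build_regions <- function(leads, map, width_cM = 0.25,
                          label = "query_regions") {
  layout <- track_layout(leads)
  pdf <- track_points(leads)
  rows <- lapply(seq_len(nrow(pdf)), function(i)
    build_region(pdf$pos[i], map, pdf$chrom[i], layout, width_cM))
  df <- do.call(rbind, rows)
  segment_track(df$chrom, df$start, df$end, layout, label)
}
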