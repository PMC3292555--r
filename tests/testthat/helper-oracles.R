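# Per-base boolean-array oracles and random fixture generators.  The
# oracles are deliberately brute force (one logical per base on tiny
# genomes) and independent of the interval arithmetic they check.

# Logical mask of length G for 0-based half-open intervals: base b (0-based)
# is element b + 1.
oracle_mask <- function(starts, ends, G) {
  v <- logical(G)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) v[(starts[i] + 1):ends[i]] <- TRUE
  v
}

# Mask of one chromosome of a SegmentTrack.
track_mask <- function(track, chrom, G) {
  df <- track_intervals(track)
  i <- df$chrom == chrom
  oracle_mask(df$start[i], df$end[i], G)
}

# Mask back to sorted 0-based half-open intervals.
mask_to_intervals <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Random raw (possibly overlapping) intervals on a single chromosome.
random_raw_intervals <- function(G, n, max_len = 50) {
  s <- sample.int(G, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = "c1", start = s, end = pmin(s + len, G))
}

one_chrom_layout <- function(G) genome_layout("c1", G)

random_track <- function(G, n, layout = one_chrom_layout(G),
                         label = "t", max_len = 50) {
  df <- random_raw_intervals(G, n, max_len)
  segment_track(df$chrom, df$start, df$end, layout, label)
}

random_point_track <- function(G, n, layout = one_chrom_layout(G)) {
  pos <- sample.int(G, n) - 1L
  point_track(sprintf("p%d", seq_len(n)), rep("c1", n), pos, layout)
}

# Independent step-up FDR oracle (textbook definition, not p.adjust).
stepup_fdr_oracle <- function(p, q) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  below <- which(sorted <= q * seq_len(n) / n)
  reject <- logical(n)
  if (length(below) > 0) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

# Exact case/control permutation p-value by exhaustive enumeration of all
# label arrangements with a fixed case count.
exact_label_perm_p <- function(ov, n_case, observed) {
  combos <- utils::combn(length(ov), n_case)
  stats <- apply(combos, 2, function(idx) sum(ov[idx]))
  mean(stats >= observed)
}
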