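# Internal helpers: typed conditions, seed substreams, and fast interval
# arithmetic on plain start/end integer vectors (0-based half-open "runs").
# The run helpers back the Monte Carlo loops, where building S4 objects per
# null sample would dominate the runtime; their results are cross-checked
# against the GenomicRanges-backed public operations in the test suite.

.stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "trackenrich_error"),
                      call = call))
}

# Deterministic substream seed from a master seed and a string key.
# Kept below 2^31 - 1; exact in double arithmetic (< 2^53 throughout).
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 9973 + 1) %% 2147483647)
}

# -- run-vector primitives -------------------------------------------------
# A "run set" is a pair of equal-length numeric vectors (s, e) with s < e,
# not necessarily sorted or disjoint unless stated.

# Total covered bases of an arbitrary run set (merges internally).
.runs_covered <- function(s, e) {
  n <- length(s)
  if (n == 0L) return(0)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  new <- c(TRUE, s[-1L] > cm[-n])
  grp_start <- s[new]
  grp_end <- cm[c(which(new)[-1L] - 1L, n)]
  sum(grp_end - grp_start)
}

# Merge an arbitrary run set into sorted disjoint runs, coalescing adjacency.
.runs_merge <- function(s, e) {
  n <- length(s)
  if (n == 0L) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  new <- c(TRUE, s[-1L] > cm[-n])
  list(s = s[new], e = cm[c(which(new)[-1L] - 1L, n)])
}

# Overlap bp between two disjoint run sets, via inclusion-exclusion.
.runs_overlap_bp <- function(sa, ea, sb, eb) {
  sum(ea - sa) + sum(eb - sb) - .runs_covered(c(sa, sb), c(ea, eb))
}

# Number of points (0-based positions) lying inside sorted disjoint runs.
.runs_count_points <- function(pos, s, e) {
  if (length(s) == 0L || length(pos) == 0L) return(0L)
  idx <- findInterval(pos, s)
  sum(idx >= 1L & pos < e[pmax(idx, 1L)])
}

# Permute the segment-length and gap-length multisets of sorted disjoint
# runs confined to a single region [b0, b1); segments and gaps are each
# independently uniformly permuted and reassembled gap,seg,...,gap.
# Preserves both multisets exactly; uses the current RNG state.
.runs_randomize <- function(s, e, b0, b1) {
  n <- length(s)
  if (n == 0L) return(list(s = s, e = e))
  len <- e - s
  gap <- c(s, b1) - c(b0, e)
  lp <- len[sample.int(n)]
  gp <- gap[sample.int(n + 1L)]
  cg <- cumsum(gp)[seq_len(n)]
  cl <- c(0, cumsum(lp))[seq_len(n)]
  ns <- b0 + cg + cl
  list(s = ns, e = ns + lp)
}

# Boolean combination of two sorted disjoint run sets via an elementary-
# interval sweep.  `op(in_a, in_b)` returns which elementary intervals to
# keep; consecutive kept intervals are coalesced.
.runs_op2 <- function(s1, e1, s2, e2, op) {
  pts <- sort(unique(c(s1, e1, s2, e2)))
  if (length(pts) < 2L) return(list(s = numeric(0), e = numeric(0)))
  a <- pts[-length(pts)]
  b <- pts[-1L]
  in1 <- if (length(s1) == 0L) rep(FALSE, length(a)) else {
    i <- findInterval(a, s1)
    i >= 1L & a < e1[pmax(i, 1L)]
  }
  in2 <- if (length(s2) == 0L) rep(FALSE, length(a)) else {
    i <- findInterval(a, s2)
    i >= 1L & a < e2[pmax(i, 1L)]
  }
  keep <- op(in1, in2)
  r <- rle(keep)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  list(s = a[idx_start[r$values]], e = b[idx_end[r$values]])
}
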