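test_that("coverage_fraction matches forced arithmetic and errors on empty reference", {
  lo <- genome_layout("c1", 100)
  ref <- segment_track("c1", 0, 20, lo, "ref")
  q <- segment_track("c1", 5, 25, lo, "q")
  expect_equal(coverage_fraction(ref, q), 15 / 20)
  expect_equal(coverage_fraction(ref, segment_track("c1", 0, 100, lo, "all")), 1)
  empty <- segment_track(character(0), numeric(0), numeric(0), lo, "e")
  expect_error(coverage_fraction(empty, q),
               class = "undefined_proportion_error")
  bin <- data.frame(chrom = "c1", start = 50, end = 100)
  expect_error(coverage_fraction(ref, q, within = bin),
               class = "undefined_proportion_error")
})

test_that("enrichment_ratio matches forced arithmetic and edge conventions", {
  lo <- genome_layout("c1", 100)
  state <- segment_track("c1", 0, 10, lo, "AP")
  q <- segment_track("c1", 0, 20, lo, "q")
  expect_equal(enrichment_ratio(state, q), (10 / 10) / (10 / 90))  # 9.0
  whole <- segment_track("c1", 0, 100, lo, "q")
  expect_equal(enrichment_ratio(state, whole), 1)
  disjoint <- segment_track("c1", 50, 60, lo, "q")
  expect_equal(enrichment_ratio(state, disjoint), 0)
  inside_only <- segment_track("c1", 2, 8, lo, "q")
  expect_error(enrichment_ratio(state, inside_only),
               class = "division_undefined_error")
})

test_that("mc_pvalue follows the floor and tie conventions", {
  expect_equal(mc_pvalue(4, c(1, 2, 3)), 1 / 3)       # k = 0 floored to 1
  expect_equal(mc_pvalue(2, c(1, 2, 3)), 2 / 3)       # tie counts as extreme
  expect_error(mc_pvalue(1, numeric(0)), class = "precondition_error")
  expect_error(mc_pvalue(NA_real_, 1:3), class = "precondition_error")
  # monotone non-increasing in the observed statistic
  set.seed(31)
  for (rep in 1:50) {
    samples <- rpois(sample(5:200, 1), lambda = 20)
    obs <- sort(sample(0:40, 2))
    expect_gte(mc_pvalue(obs[1], samples), mc_pvalue(obs[2], samples))
  }
})

test_that("bh_fdr matches forced examples and an independent step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.2), q = 0.1), c(TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), q = 0.1), rep(FALSE, 5))
  expect_error(bh_fdr(c(0.5, 0)), class = "validation_error")
  set.seed(32)
  for (rep in 1:1000) {
    n <- sample(1:40, 1)
    p <- round(runif(n), 3)
    p[p == 0] <- 0.001
    q <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q), stepup_fdr_oracle(p, q))
  }
})

test_that("randomize_track has no freedom for a bin-filling segment", {
  lo <- genome_layout("c1", 10)
  tr <- segment_track("c1", 0, 10, lo, "t")
  for (seed in 1:5)
    expect_equal(track_intervals(randomize_track(tr, seed = seed)),
                 track_intervals(tr))
})

test_that("randomize_track conserves covered bp and segment-length multiset", {
  set.seed(33)
  for (rep in 1:200) {
    G <- sample(100:2000, 1)
    lo <- one_chrom_layout(G)
    tr <- random_track(G, sample(1:30, 1), lo)
    r <- randomize_track(tr)
    expect_equal(covered_bp(r), covered_bp(tr))
    di <- track_intervals(tr); dr <- track_intervals(r)
    expect_equal(sort(dr$end - dr$start), sort(di$end - di$start))
    # output stays inside the layout and is disjoint
    expect_true(all(dr$start >= 0 & dr$end <= G))
    expect_true(all(dr$start[-1] >= dr$end[-nrow(dr)]))
  }
})

test_that("randomization requires tracks restricted to the bin", {
  lo <- genome_layout("c1", 100)
  tr <- segment_track("c1", 30, 60, lo, "t")
  spanning_bin <- data.frame(chrom = "c1", start = 0, end = 50)
  expect_error(randomize_track(tr, within = spanning_bin),
               class = "precondition_error")
  outside_bin <- data.frame(chrom = "c1", start = 70, end = 100)
  expect_error(randomize_track(tr, within = outside_bin),
               class = "precondition_error")
})

test_that("fast-path overlap used by the Monte Carlo loop matches overlap_bp", {
  set.seed(34)
  for (rep in 1:200) {
    G <- sample(100:2000, 1)
    lo <- one_chrom_layout(G)
    a <- random_track(G, sample(1:40, 1), lo, "a")
    b <- random_track(G, sample(1:40, 1), lo, "b")
    da <- track_intervals(a); db <- track_intervals(b)
    expect_equal(
      trackenrich:::.runs_overlap_bp(da$start, da$end, db$start, db$end),
      overlap_bp(a, b))
  }
})

test_that("an unbeatable observed overlap reaches the p-value floor", {
  set.seed(35)
  lo <- genome_layout("c1", 10000)
  s <- sort(sample(seq(0, 9900, by = 60), 15))
  lens <- sample(10:45, 15, replace = TRUE)
  state <- segment_track(rep("c1", 15), s, s + lens, lo, "dense")
  res <- test_overlap_global(state, state, null_config(n_samples = 200,
                                                       seed = 9))
  expect_equal(res$observed, covered_bp(state))
  expect_equal(res$p_value, 1 / 200)
})

test_that("global test is deterministic for a fixed seed", {
  cfg <- sim_config(c(c1 = 2e5), seed = 44,
                    states = data.frame(label = "S", mean_len = 2000,
                                        fraction = 0.2),
                    query = list(n_regions = 10, mean_width = 1000,
                                 enrichment_factor = 2, target = "S"))
  states <- simulate_chromatin(cfg)
  q <- simulate_query(cfg, states)
  r1 <- test_overlap_global(states$S, q, null_config(100, seed = 5))
  r2 <- test_overlap_global(states$S, q, null_config(100, seed = 5))
  expect_identical(r1, r2)
  r3 <- test_overlap_global(states$S, q, null_config(100, seed = 6))
  expect_false(identical(r3$p_value, r1$p_value) &&
               identical(r3$null_mean, r1$null_mean))
})

test_that("local test excludes query-free bins and flags a planted bin", {
  lo <- genome_layout(c("c1", "c2", "c3"), c(50000, 50000, 50000))
  cyto <- data.frame(
    chrom = rep(c("c1", "c2", "c3"), each = 2),
    start = rep(c(0, 25000), 3), end = rep(c(25000, 50000), 3),
    band = rep(c("p11", "q11"), 3), stain = "gneg")
  bins <- partition_arms(lo, cyto)
  # identical state layout on all chromosomes, irregular (distinct) gaps
  s <- c(0, 3000, 9000, 14000, 21000, 26000, 30000, 36000, 41000, 47000)
  state <- segment_track(rep(c("c1", "c2", "c3"), each = length(s)),
                         rep(s, 3), rep(s + 1000, 3), lo, "S")
  # query hugs the state on c1p, avoids it on c2, is absent from c3
  q <- segment_track(c(rep("c1", 5), "c2", "c2"),
                     c(s[1:5], 6000, 28000), c(s[1:5] + 1100, 7200, 29200),
                     lo, "q")
  res <- test_overlap_local(state, q, bins, null_config(400, seed = 2),
                            fdr_q = 0.10)
  expect_setequal(attr(res, "excluded_bins"), c("c1q", "c3p", "c3q"))
  expect_setequal(res$bin_id, c("c1p", "c2p", "c2q"))
  expect_true(res$fdr_significant[res$bin_id == "c1p"])
  expect_false(any(res$fdr_significant[res$bin_id != "c1p"]))
  expect_true(all(res$p_value >= 1 / 400 & res$p_value <= 1))
})

test_that("single-bin local test agrees with the global test", {
  cfg <- sim_config(c(c1 = 2e5), seed = 77,
                    states = data.frame(label = "S", mean_len = 2000,
                                        fraction = 0.2),
                    query = list(n_regions = 15, mean_width = 1000,
                                 enrichment_factor = 2, target = "S"))
  states <- simulate_chromatin(cfg)
  q <- simulate_query(cfg, states)
  g <- test_overlap_global(states$S, q, null_config(400, seed = 3))
  l <- test_overlap_local(states$S, q,
                          whole_genome_bins(trackenrich::track_layout(states$S)),
                          null_config(400, seed = 3))
  expect_equal(l$observed_overlap, g$observed)
  expect_equal(l$enrichment, g$enrichment)
  # same null model: null means agree within Monte Carlo error
  expect_lt(abs(l$null_mean - g$null_mean),
            4 * max(l$null_sd, g$null_sd) / sqrt(400) * sqrt(2) + 1e-9)
})

test_that("self-null p-values are calibrated (stochastically >= uniform)", {
  # the observed state track is itself one draw from the randomization
  # null, so observed and null statistics are exchangeable by construction
  lo <- genome_layout("c1", 5e5)
  set.seed(37)
  s0 <- sort(sample(seq(0, 5e5 - 2000, by = 12000), 35))
  state0 <- segment_track(rep("c1", 35), s0,
                          s0 + sample(200:2000, 35, replace = TRUE), lo, "S")
  q0 <- sort(sample(seq(0, 5e5 - 4000, by = 40000), 12))
  query <- segment_track(rep("c1", 12), q0,
                         q0 + sample(1000:4000, 12, replace = TRUE), lo, "q")
  n_rep <- 500
  ps <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    state_i <- randomize_track(state0, seed = 30000 + i)
    ps[i] <- test_overlap_global(state_i, query,
                                 null_config(200, seed = i))$p_value
  }
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # and not anti-conservative anywhere obvious in the lower tail
  expect_lte(mean(ps <= 0.01), 0.025)
})
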