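# End-to-end orchestration: validated configs, file-in/file-out runs,
# determinism, and the three-way significance labelling.

write_fixture_files <- function(dir, seed = 91) {
  cfg <- sim_config(c(c1 = 3e5, c2 = 2e5), seed = seed,
                    states = data.frame(label = c("AP", "WE"),
                                        mean_len = c(1000, 3000),
                                        fraction = c(0.1, 0.15)),
                    query = list(n_regions = 25, mean_width = 800,
                                 enrichment_factor = 3, target = "AP"),
                    points = list(n_points = 60, multiplier = 2,
                                  target = "AP"))
  states <- simulate_chromatin(cfg)
  q <- simulate_query(cfg, states)
  pts <- simulate_points(cfg, states)
  layout <- attr(states, "layout")
  paths <- list(
    layout = file.path(dir, "genome.chrom.sizes"),
    states = file.path(dir, "states.bed"),
    control = file.path(dir, "control.bed"),
    query = file.path(dir, "query.bed"),
    points = file.path(dir, "points.tsv"),
    cytoband = file.path(dir, "cytoband.tsv"),
    map = file.path(dir, "map.tsv"))
  lens <- GenomeInfoDb::seqlengths(layout)
  writeLines(sprintf("%s\t%d", names(lens), lens), paths$layout)
  seg <- rbind(cbind(track_intervals(states$AP), label = "AP"),
               cbind(track_intervals(states$WE), label = "WE"))
  writeLines(sprintf("%s\t%s\t%s\t%s", seg$chrom,
                     format(seg$start, scientific = FALSE, trim = TRUE),
                     format(seg$end, scientific = FALSE, trim = TRUE),
                     seg$label), paths$states)
  # control cell type: same states, independently simulated
  cfg2 <- sim_config(c(c1 = 3e5, c2 = 2e5), seed = seed + 1,
                     states = cfg$states)
  ctrl <- simulate_chromatin(cfg2)
  seg2 <- rbind(cbind(track_intervals(ctrl$AP), label = "AP"),
                cbind(track_intervals(ctrl$WE), label = "WE"))
  writeLines(sprintf("%s\t%s\t%s\t%s", seg2$chrom,
                     format(seg2$start, scientific = FALSE, trim = TRUE),
                     format(seg2$end, scientific = FALSE, trim = TRUE),
                     seg2$label), paths$control)
  write_bed(q, paths$query)
  write_points(pts, paths$points)
  writeLines(c("c1\t0\t150000\tp11\tgneg", "c1\t150000\t300000\tq11\tgneg",
               "c2\t0\t200000\tq11\tgneg"), paths$cytoband)
  writeLines(c("chrom\tpos\tcM", "c1\t0\t0", "c1\t300000\t0.6",
               "c2\t0\t0", "c2\t200000\t0.4"), paths$map)
  paths
}

test_that("run_config validates mode and inputs before any computation", {
  expect_error(run_config("frobnicate"), class = "validation_error")
  expect_error(run_config("region-overlap", states = NULL,
                          query = "q.bed", layout = "l.sizes"),
               class = "validation_error")
  expect_error(run_config("region-overlap", states = "/nonexistent.bed",
                          query = "/nonexistent.bed",
                          layout = "/nonexistent.sizes"),
               class = "validation_error")
})

test_that("region-overlap runs end to end and is byte-identical per seed", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  rc1 <- run_config("region-overlap", states = paths$states,
                    query = paths$query, layout = paths$layout,
                    n_samples = 200, seed = 5, out_dir = out1)
  tab1 <- run_analysis(rc1)
  rc2 <- run_config("region-overlap", states = paths$states,
                    query = paths$query, layout = paths$layout,
                    n_samples = 200, seed = 5, out_dir = out2)
  run_analysis(rc2)
  expect_identical(readLines(file.path(out1, "results.tsv")),
                   readLines(file.path(out2, "results.tsv")))
  expect_setequal(tab1$track_label, c("AP", "WE"))
  expect_true(all(tab1$p_value >= 1 / 200 & tab1$p_value <= 1))
  # the planted AP enrichment dominates the WE one
  expect_gt(tab1$enrichment[tab1$track_label == "AP"],
            tab1$enrichment[tab1$track_label == "WE"])
  log <- readLines(file.path(out1, "run.log"))
  expect_true(any(grepl("seed: 5", log)))
  expect_true(any(grepl("n_samples: 200", log)))
})

test_that("local-overlap logs excluded bins and applies FDR flags", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  out <- file.path(dir, "out_local")
  rc <- run_config("local-overlap", states = paths$states,
                   query = paths$query, layout = paths$layout,
                   cytoband = paths$cytoband, n_samples = 100, seed = 2,
                   out_dir = out)
  tab <- run_analysis(rc)
  expect_true(all(tab$bin_id %in% c("c1p", "c1q", "c2q")))
  expect_true(is.logical(tab$fdr_significant))
  back <- read_results(file.path(out, "results.tsv"))
  expect_equal(nrow(back), nrow(tab))
})

test_that("case-control and point-overlap modes produce labelled rows", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  rc_cc <- run_config("case-control", states = paths$states,
                      control_states = paths$control, query = paths$query,
                      layout = paths$layout, n_samples = 100, seed = 3,
                      out_dir = file.path(dir, "out_cc"))
  tab_cc <- run_analysis(rc_cc)
  expect_setequal(tab_cc$track_label, c("AP", "WE"))
  rc_pt <- run_config("point-overlap", states = paths$states,
                      points = paths$points, layout = paths$layout,
                      n_samples = 100, seed = 3,
                      out_dir = file.path(dir, "out_pt"))
  tab_pt <- run_analysis(rc_pt)
  expect_setequal(tab_pt$track_label, c("AP", "WE"))
  expect_true(all(tab_pt$observed_overlap <= 60))
})

test_that("build-regions mode writes a merged BED of cM windows", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  lo <- read_chrom_sizes(paths$layout)
  leads <- point_track(c("rs1", "rs2"), c("c1", "c2"), c(150000, 100000), lo)
  lead_path <- file.path(dir, "leads.tsv")
  write_points(leads, lead_path)
  out <- file.path(dir, "out_regions")
  rc <- run_config("build-regions", points = lead_path, map = paths$map,
                   layout = paths$layout, width_cM = 0.25, out_dir = out)
  tr <- run_analysis(rc)
  back <- read_bed(file.path(out, "regions.bed"), lo)
  expect_equal(track_intervals(back), track_intervals(tr))
  # 0.25 cM at 2 cM/Mb is 125 kb per region
  widths <- with(track_intervals(back), end - start)
  expect_equal(widths, c(125000, 125000))
})

test_that("significance labels follow the YES / Maybe / NO thresholds", {
  expect_equal(significance_label(c(0.00005, 0.0413, 0.181, 1)),
               c("YES", "Maybe", "NO", "NO"))
  expect_equal(significance_label(0.02, alpha_strict = 0.05), "YES")
})
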