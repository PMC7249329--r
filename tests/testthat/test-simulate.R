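small_config <- function(...) {
  simulation_config(n_chromosomes = 2L, chrom_length = 5e6,
                    n_probes = 3000L, n_genes = 300L,
                    n_background_peaks = 1000L,
                    n_de_up = 30L, n_de_down = 40L,
                    n_accessible_genes = 60L, n_methylated_genes = 50L,
                    n_de_accessible = 10L, n_de_methylated = 8L,
                    n_triple = 3L, ...)
}

test_that("identical config and seed reproduce every file byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(d1, small_config(), seed = 11)
  simulate_study(d2, small_config(), seed = 11)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_study(d3, small_config(), seed = 12)
  expect_false(identical(readLines(file.path(d1, "beta.tsv")),
                         readLines(file.path(d3, "beta.tsv"))))
})

test_that("generated LAD coverage matches the configured fraction", {
  fracs <- vapply(1:8, function(s) {
    g <- make_genome(simulation_config(n_chromosomes = 1L,
                                       chrom_length = 1e7,
                                       lad_fraction = 0.5,
                                       n_probes = 500L, n_genes = 50L),
                     seed = s)
    sum(g$laminA$end - g$laminA$start) / 1e7
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("zero LAD fraction yields an empty track and all-non-LAD probes", {
  g <- make_genome(small_config(lad_fraction = 1e-9,
                                lad_mean_length = 1e4), seed = 2)
  expect_lt(sum(g$laminA$end - g$laminA$start), 1e5)
  expect_lt(mean(g$annot$in_laminA), 0.02)
  # invalid configs rejected
  expect_error(make_genome(small_config(lad_fraction = 1)), "< 1")
  expect_error(make_genome(small_config(lad_mean_length = 1e9)),
               "exceeds chromosome")
  expect_error(simulation_config(not_a_key = 1), "unknown")
})

test_that("planted methylation effects appear where planted", {
  cfg <- small_config()
  g <- make_genome(cfg, seed = 3)
  m <- make_methylation(g, cfg, seed = 3)
  expect_true(all(m$beta >= 0 & m$beta <= 1))
  aff <- m$truth$affected_probes
  expect_true(all(aff %in% g$annot$probe_id[g$annot$in_laminA]))
  # case2 samples are globally shifted toward 0.5 relative to case1
  hmd <- g$annot$probe_id[g$annot$in_hmd & !g$annot$in_laminA]
  c1 <- m$sheet$sample_id[m$sheet$subgroup == "case1"]
  c2 <- m$sheet$sample_id[m$sheet$subgroup == "case2"]
  expect_lt(mean(m$beta[hmd, c2]), mean(m$beta[hmd, c1]) - 0.03)
  # with only the LAD effect planted, its delta is recovered precisely
  cfg_lad <- small_config(pm_shift_strength = 0)
  m2 <- make_methylation(g, cfg_lad, seed = 3)
  is_case <- m2$sheet$group == "case"
  aff2 <- m2$truth$affected_probes
  delta <- rowMeans(m2$beta[aff2, is_case]) -
    rowMeans(m2$beta[aff2, !is_case])
  expect_lt(abs(median(delta) - cfg$lad_delta_beta), 0.01)
  # an infeasible planted effect errors
  expect_error(make_methylation(g, small_config(lad_delta_beta = 0.5),
                                seed = 3), "valid beta range")
})

test_that("null generator calibrates the moderated F-test", {
  cfg <- small_config(lad_delta_beta = 0, pm_shift_strength = 0)
  g <- make_genome(cfg, seed = 5)
  m <- make_methylation(g, cfg, seed = 5)
  res <- fit_moderated_f(m$beta, m$sheet)
  rej <- mean(res$p_value < 0.05)
  ci <- qbinom(c(0.005, 0.995), nrow(res), 0.05) / nrow(res)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("differential peaks honour direction bookkeeping and placement", {
  cfg <- small_config()
  g <- make_genome(cfg, seed = 7)
  pk <- make_diff_peaks(g, cfg, seed = 7)
  expect_equal(sum(pk$peaks$direction == "gained"), cfg$n_gained_peaks)
  expect_equal(sum(pk$peaks$direction == "lost"), cfg$n_lost_peaks)
  expect_equal(sum(pk$peaks$significant),
               cfg$n_gained_peaks + cfg$n_lost_peaks)
  # gained peaks sit in LADs far above the background rate
  in_lad <- pk$truth$in_laminA
  gained_rate <- mean(in_lad[pk$peaks$direction == "gained"])
  stable_rate <- mean(in_lad[pk$peaks$direction == "stable"])
  expect_gt(gained_rate, 1.5 * stable_rate)
  # enrichment factor 1 -> fold compatible with +1 (null placement)
  cfg1 <- small_config(lad_peak_enrichment_gained = 1,
                       lad_peak_enrichment_lost = 1)
  pk1 <- make_diff_peaks(g, cfg1, seed = 7)
  r <- fold_enrichment(pk1$peaks$direction == "gained",
                       overlaps_any(pk1$peaks, g$laminA))
  expect_lt(abs(r$signed_fold), 1.35)
})

test_that("expression generator plants the multi-omic Venn and proximity", {
  cfg <- small_config()
  g <- make_genome(cfg, seed = 9)
  ex <- make_expression(g, cfg, seed = 9)
  expect_equal(sum(ex$expression$significant),
               cfg$n_de_up + cfg$n_de_down)
  ov <- multiomic_overlap(ex$gene_sets$de, ex$gene_sets$accessible,
                          ex$gene_sets$methylated)
  expect_equal(unname(ov$counts["de_and_accessible"]),
               cfg$n_de_accessible)
  expect_equal(unname(ov$counts["de_and_methylated"]),
               cfg$n_de_methylated)
  expect_equal(unname(ov$counts["de_and_accessible_and_methylated"]),
               cfg$n_triple)
  # the accessibility-coupled DE set is LAD-proximal by construction
  d <- ex$truth$lad_distance[ex$truth$de_accessible]
  expect_true(all(d <= cfg$lad_proximal_max))
  # table round-trips through the TSV writer/reader unchanged
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(ex$expression, path)
  back <- read_tsv_table(path)
  expect_equal(back$gene_id, ex$expression$gene_id)
  expect_equal(back$q_value, ex$expression$q_value, tolerance = 1e-12)
})

test_that("noise-free synthetic clock round-trips exactly", {
  cfg <- small_config(clock_age_sd = 0)
  g <- make_genome(cfg, seed = 13)
  m <- make_methylation(g, cfg, seed = 13)
  ck <- make_clock(m$sheet, cfg, seed = 13)
  est <- apply_clock(ck$clock_beta, ck$clock, sheet = m$sheet)
  expect_equal(est$dnam_age, unname(ck$truth$dnam_age), tolerance = 1e-8)
  # planted subgroup offsets separate the age-acceleration medians
  accel <- age_acceleration(est, m$sheet$subgroup)
  expect_equal(accel$median_delta_age[accel$subgroup == "case2"],
               cfg$delta_age_case2, tolerance = 1e-6)
  expect_equal(accel$median_delta_age[accel$subgroup == "case1"],
               cfg$delta_age_case1, tolerance = 1e-6)
  # same seed -> identical clock
  ck2 <- make_clock(m$sheet, cfg, seed = 13)
  expect_identical(ck, ck2)
})
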