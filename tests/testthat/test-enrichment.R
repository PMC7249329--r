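test_that("fold_enrichment computes expected counts and signed folds", {
  # universe 1000, 100 in track, 50 selected, 25 observed
  sel <- rep(FALSE, 1000); sel[1:50] <- TRUE
  trk <- rep(FALSE, 1000); trk[c(1:25, 101:175)] <- TRUE
  r <- fold_enrichment(sel, trk)
  expect_equal(r$expected, 5)
  expect_equal(r$observed, 25)
  expect_equal(r$signed_fold, 5.0)
  # depletion convention: observed 2, expected 5 -> -2.5
  sel2 <- rep(FALSE, 1000); sel2[1:50] <- TRUE
  trk2 <- rep(FALSE, 1000); trk2[c(1:2, 101:198)] <- TRUE
  r2 <- fold_enrichment(sel2, trk2)
  expect_equal(r2$expected, 5)
  expect_equal(r2$signed_fold, -2.5)
  # exact independence: +1.0, chi-squared 0, p 1 (correction capped)
  sel3 <- rep(c(TRUE, FALSE), c(100, 900))
  trk3 <- rep(FALSE, 1000); trk3[c(1:10, 101:190)] <- TRUE
  r3 <- fold_enrichment(sel3, trk3)
  expect_equal(r3$signed_fold, 1.0)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  # degenerate margins error
  expect_error(fold_enrichment(rep(FALSE, 10), trk3[1:10]), "empty")
  expect_error(fold_enrichment(sel3[1:10], rep(TRUE, 10)), "degenerate")
})

test_that("fold_enrichment counts and statistic match brute-force recount", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(100:5000, 1)
    sel <- runif(n) < runif(1, 0.05, 0.5)
    trk <- runif(n) < runif(1, 0.1, 0.6)
    if (sum(sel) == 0 || sum(trk) == 0 || sum(trk) == n) next
    r <- fold_enrichment(sel, trk)
    obs <- sum(vapply(seq_len(n), function(j) sel[j] && trk[j],
                      logical(1)))
    expect_equal(r$observed, obs)
    expect_equal(r$expected, sum(sel) * sum(trk) / n)
    tab <- matrix(c(obs, sum(sel) - obs, sum(trk) - obs,
                    n - sum(sel) - sum(trk) + obs), 2)
    expect_equal(r$statistic, hand_yates_chi2(tab), tolerance = 1e-10)
    # and against R's chisq.test with continuity correction
    if (all(tab > 0)) {
      ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
      expect_equal(r$statistic, unname(ct$statistic), tolerance = 1e-10)
      expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)
    }
  }
})

test_that("doubling all counts keeps the fold and grows the statistic", {
  sel <- rep(c(TRUE, FALSE), c(200, 800))
  trk <- rep(FALSE, 1000); trk[c(1:80, 201:400)] <- TRUE
  r1 <- fold_enrichment(sel, trk)
  r2 <- fold_enrichment(rep(sel, 2), rep(trk, 2))
  expect_equal(r2$signed_fold, r1$signed_fold)
  expect_gt(r2$statistic, r1$statistic)
})

test_that("fisher_enrichment reports the cross-product OR and exact p", {
  r <- fisher_enrichment(matrix(c(1, 10, 9, 90), 2))
  expect_equal(r$odds_ratio, 1.0)
  expect_equal(r$p, 1.0)
  r2 <- fisher_enrichment(matrix(c(3, 1, 1, 3), 2))
  expect_equal(r2$odds_ratio, 9.0)
  expect_equal(r2$p, 34 / 70, tolerance = 1e-12)
  # zero cell: infinite OR, finite p
  r3 <- fisher_enrichment(matrix(c(5, 0, 2, 6), 2))
  expect_equal(r3$odds_ratio, Inf)
  expect_lt(r3$p, 1)
  expect_error(fisher_enrichment(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
})

test_that("fisher p matches full hypergeometric enumeration", {
  set.seed(23)
  for (i in 1:100) {
    repeat {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
          sum(tab) <= 60) break
    }
    expect_equal(fisher_enrichment(tab)$p, enumerate_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("Fisher and Yates chi-squared p agree on large balanced tables", {
  set.seed(29)
  for (i in 1:20) {
    tab <- matrix(sample(40:400, 4, replace = TRUE), 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(e) < 20) next
    sel <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tab[1, 1], tab[1, 2],
                                              tab[2, 1], tab[2, 2]))
    trk <- rep(c(TRUE, FALSE, TRUE, FALSE), c(tab[1, 1], tab[1, 2],
                                              tab[2, 1], tab[2, 2]))
    p_chi <- fold_enrichment(sel, trk)$p_value
    p_fish <- fisher_enrichment(tab)$p
    expect_lt(abs(p_chi - p_fish), 0.03)
  }
})

test_that("peak_feature_distribution counts non-exclusive overlaps", {
  peaks <- genomic_track("chr1", seq(0, 900, 100), seq(50, 950, 100))
  laminA <- genomic_track("chr1", 0, 360)         # peaks 1-4 overlap
  genes <- genomic_track("chr1", 300, 460)        # peaks 4, 5 overlap
  res <- peak_feature_distribution(peaks,
                                   list(laminA_LAD = laminA, genes = genes),
                                   lad_tracks = "laminA_LAD")
  expect_equal(res$fraction[res$feature == "laminA_LAD"], 0.4)
  expect_equal(res$count[res$feature == "genes"], 2)
  expect_equal(res$count[res$feature == "non_LAD"], 6)
  # a peak inside both a gene and a LAD is counted once in each
  expect_gt(sum(res$count[res$feature != "non_LAD"]), 5)
  # no overlaps at all: non-LAD fraction 1
  far <- genomic_track("chr2", 0, 100)
  res2 <- peak_feature_distribution(peaks, list(laminA_LAD = far),
                                    lad_tracks = "laminA_LAD")
  expect_equal(res2$fraction, c(0, 1))
})

test_that("peak counts are invariant to peak order and track splitting", {
  set.seed(37)
  pk <- random_track(40)
  peaks <- genomic_track(pk$chrom, pk$start, pk$end)
  whole <- genomic_track("chr1", 1000, 5000)
  split2 <- genomic_track(c("chr1", "chr1"), c(1000, 3000), c(3000, 5000))
  r_whole <- peak_feature_distribution(peaks, list(t = whole))
  r_split <- peak_feature_distribution(peaks, list(t = split2))
  expect_equal(r_whole$count, r_split$count)
})

test_that("stratified_delta_beta recovers planted shifts per stratum", {
  set.seed(41)
  n <- 3000
  ids <- sprintf("cg%05d", seq_len(n))
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:12),
                      group = rep(c("case", "control"), each = 6))
  lad <- seq_len(2000)      # planted +0.10 stratum
  mu <- matrix(0.5, n, 12)
  mu[lad, 1:6] <- 0.6
  beta <- matrix(pmin(1, pmax(0, rnorm(n * 12, mu, 0.03))), n, 12,
                 dimnames = list(ids, sheet$sample_id))
  res <- stratified_delta_beta(beta, sheet,
                               strata = list(all = rep(TRUE, n),
                                             LAD = seq_len(n) %in% lad,
                                             non_LAD = !(seq_len(n) %in%
                                                           lad)))
  lad_row <- res[res$stratum == "LAD", ]
  expect_lt(abs(lad_row$median_delta - 0.10), 0.01)
  expect_lt(lad_row$p, 1e-10)
  expect_lt(abs(res$median_delta[res$stratum == "non_LAD"]), 0.01)
  # identical groups: median 0, p near 1
  beta_null <- cbind(beta[, 7:12], beta[, 7:12])
  colnames(beta_null) <- sheet$sample_id
  res_null <- stratified_delta_beta(beta_null, sheet,
                                    strata = list(all = rep(TRUE, n)))
  expect_equal(res_null$median_delta, 0)
  expect_equal(res_null$p, 1)
  # empty and singleton strata error with the stratum name
  expect_error(stratified_delta_beta(beta, sheet,
                                     strata = list(bad = rep(FALSE, n))),
               "bad")
  one <- rep(FALSE, n); one[1] <- TRUE
  expect_error(stratified_delta_beta(beta, sheet, strata = list(solo = one)),
               "single probe")
})

test_that("probe membership and the enrichment suite wire together", {
  annot <- data.frame(probe_id = sprintf("cg%03d", 1:100),
                      chrom = "chr1", pos = seq(10, 1000, 10))
  lad <- genomic_track("chr1", 0, 500, track_name = "laminA_LAD")
  mem <- probe_track_membership(annot, list(laminA_LAD = lad))
  expect_equal(sum(mem[, "laminA_LAD"]), 50)   # positions 10..500
  diff_table <- data.frame(probe_id = annot$probe_id,
                           delta_beta = rep(c(0.2, -0.2), 50),
                           significant = rep(c(TRUE, FALSE), c(40, 60)))
  suite <- enrichment_suite(diff_table, mem)
  expect_setequal(suite$direction, c("all", "hyper", "hypo"))
  all_row <- suite[suite$direction == "all", ]
  expect_equal(all_row$n_selected, 40)
  expect_equal(all_row$expected, 40 * 50 / 100)
})
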