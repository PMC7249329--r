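make_two_group <- function(n_probes = 50, n1 = 5, n2 = 6, seed = 1) {
  set.seed(seed)
  beta <- matrix(runif(n_probes * (n1 + n2), 0.2, 0.8), n_probes,
                 dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                                 sprintf("S%02d", seq_len(n1 + n2))))
  sheet <- data.frame(sample_id = colnames(beta),
                      group = c(rep("case", n1), rep("control", n2)))
  list(beta = beta, sheet = sheet)
}

test_that("filter_probes applies detection and flag rules", {
  fx <- make_two_group(n_probes = 6)
  det <- matrix(0.001, 6, 11, dimnames = dimnames(fx$beta))
  det["cg002", 4] <- 0.02          # fails in one sample -> removed
  det["cg005", ] <- 0.005          # max detection p 0.005 -> retained
  annot <- data.frame(probe_id = rownames(fx$beta),
                      chrom = "chr1", pos = 1:6,
                      sex_chromosome = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                                         FALSE),
                      snp_affected = FALSE,
                      cross_reactive = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                         FALSE))
  res <- filter_probes(fx$beta, det, annot)
  expect_setequal(rownames(res$beta), c("cg001", "cg005", "cg006"))
  expect_equal(unname(res$removed[c("detection", "sex_chromosome",
                                    "cross_reactive", "total")]),
               c(1, 1, 1, 3))
  # retained values are untouched
  expect_equal(res$beta["cg005", ], fx$beta["cg005", ])
  # misaligned matrices error
  expect_error(filter_probes(fx$beta, det[, 1:10], annot), "misaligned")
})

test_that("bh_adjust reproduces the step-up computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # scrambled input order maps back correctly
  expect_equal(bh_adjust(c(0.04, 0.01, 0.02)), c(0.04, 0.03, 0.03))
  # monotone when sorted by p
  set.seed(1)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("welch_t matches the hand formula and handles degeneracy", {
  r <- welch_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$t, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4))
  # agrees with stats::t.test
  set.seed(3)
  x <- rnorm(8); y <- rnorm(12, 0.5, 2)
  tt <- t.test(x, y)
  r2 <- welch_t(x, y)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  # identical samples
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  # constant unequal samples
  expect_warning(r3 <- welch_t(c(1, 1), c(2, 2)), "p = 0")
  expect_equal(r3$p, 0)
})

test_that("welch_t is calibrated under the Gaussian null", {
  set.seed(11)
  n_rep <- 10000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rej[i] <- welch_t(rnorm(10), rnorm(10))$p < 0.05
  }
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("moderated F without shrinkage equals the two-group ANOVA F", {
  fx <- make_two_group(n_probes = 40, seed = 5)
  res <- fit_moderated_f(fx$beta, fx$sheet, shrink = FALSE)
  is_case <- fx$sheet$group == "case"
  for (i in c(1, 7, 23, 40)) {
    oracle <- anova_f_oracle(fx$beta[i, ], is_case)
    expect_equal(res$F_statistic[i], unname(oracle["F"]),
                 tolerance = 1e-10)
    expect_equal(res$p_value[i], unname(oracle["p"]), tolerance = 1e-10)
  }
})

test_that("variance shrinkage follows the closed-form posterior", {
  # fixed s2 = 1, dg = 13, d0 = 4, s0^2 = 2 -> (4*2 + 13*1)/17
  s2 <- 1; dg <- 13; d0 <- 4; s0sq <- 2
  expect_equal((d0 * s0sq + dg * s2) / (d0 + dg), 21 / 17)
  # the fitted table reproduces the same formula with its estimated prior
  fx <- make_two_group(n_probes = 200, seed = 8)
  res <- fit_moderated_f(fx$beta, fx$sheet, shrink = TRUE)
  prior <- attr(res, "prior")
  dg <- attr(res, "df_residual")
  expect_true(prior$d0 > 0 && prior$s0_squared > 0)
  if (is.finite(prior$d0)) {
    expect_equal(res$s2_moderated,
                 (prior$d0 * prior$s0_squared + dg * res$s2) /
                   (prior$d0 + dg))
  } else {
    expect_equal(res$s2_moderated, rep(prior$s0_squared, nrow(res)))
  }
})

test_that("prior estimation agrees with the limma empirical-Bayes fit", {
  skip_if_no_limma()
  fx <- make_two_group(n_probes = 500, seed = 13)
  res <- fit_moderated_f(fx$beta, fx$sheet, shrink = TRUE)
  sq <- limma::squeezeVar(res$s2, df = attr(res, "df_residual"))
  expect_equal(res$s2_moderated, sq$var.post, tolerance = 1e-6)
  prior <- attr(res, "prior")
  if (is.finite(prior$d0) && is.finite(sq$df.prior)) {
    expect_equal(prior$d0, sq$df.prior, tolerance = 1e-4)
    expect_equal(prior$s0_squared, sq$var.prior, tolerance = 1e-6)
  }
})

test_that("forcing an infinite prior pools all variances", {
  # under-dispersed variances (constant s2 across probes) -> d0 = Inf and
  # the F statistic is based purely on the pooled s0^2
  set.seed(2)
  n <- 300
  base <- matrix(rnorm(n * 10), n, 10)
  base <- base / sqrt(rowSums(base^2) / 8) * 0.1   # equalize residual scale
  beta <- 0.5 + base
  colnames(beta) <- sprintf("S%02d", 1:10)
  rownames(beta) <- sprintf("cg%03d", seq_len(n))
  sheet <- data.frame(sample_id = colnames(beta),
                      group = rep(c("case", "control"), each = 5))
  res <- fit_moderated_f(beta, sheet, shrink = TRUE)
  prior <- attr(res, "prior")
  expect_true(is.infinite(prior$d0))
  expect_equal(res$s2_moderated, rep(prior$s0_squared, n))
})

test_that("all-constant probes give F = 0 and p = 1, never NaN", {
  beta <- matrix(0.5, 5, 8,
                 dimnames = list(sprintf("cg%03d", 1:5),
                                 sprintf("S%02d", 1:8)))
  sheet <- data.frame(sample_id = colnames(beta),
                      group = rep(c("case", "control"), each = 4))
  res <- fit_moderated_f(beta, sheet)
  expect_equal(res$F_statistic, rep(0, 5))
  expect_equal(res$p_value, rep(1, 5))
  expect_false(anyNA(res$q_value))
})

test_that("fit_moderated_f validates its design and handles missing rows", {
  fx <- make_two_group()
  one_group <- fx$sheet
  one_group$group <- "case"
  expect_error(fit_moderated_f(fx$beta, one_group), "two groups")
  small <- fx$sheet
  small$group <- c("case", rep("control", 10))
  expect_error(fit_moderated_f(fx$beta, small), ">= 2 samples")
  beta_na <- fx$beta
  beta_na[3, 2] <- NA
  expect_warning(res <- fit_moderated_f(beta_na, fx$sheet), "dropped")
  expect_equal(nrow(res), nrow(fx$beta) - 1L)
})

test_that("delta_beta is case minus control on the beta scale", {
  fx <- make_two_group(n_probes = 10, seed = 21)
  shifted <- fx$beta
  is_case <- fx$sheet$group == "case"
  shifted[1, is_case] <- pmin(1, shifted[1, is_case] + 0.2)
  res <- fit_moderated_f(shifted, fx$sheet, shrink = FALSE)
  expect_gt(res$delta_beta[1], 0.1)
  # m-value testing keeps beta-scale means in the report
  res_m <- fit_moderated_f(shifted, fx$sheet, mvalues = TRUE)
  expect_equal(res_m$mean_beta_case, res$mean_beta_case)
  expect_equal(res_m$delta_beta, res$delta_beta)
})

test_that("beta matrix TSV round-trips", {
  fx <- make_two_group(n_probes = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(fx$beta, path)
  back <- read_beta_matrix(path)
  expect_equal(back, fx$beta)
})
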