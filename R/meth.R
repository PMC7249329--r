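#' Probe quality filtering
#'
#' Removes probes failing array quality rules before differential testing:
#' any probe whose detection p-value exceeds `det_threshold` in at least one
#' sample, plus probes flagged as sex-chromosomal, SNP-affected, or
#' cross-reactive in the annotation. Retained beta values are never
#' modified, only row membership changes.
#'
#' @param beta numeric matrix of methylation fractions (probes x samples),
#'   rownames = probe ids.
#' @param detection_p numeric matrix aligned to `beta` (same dimnames).
#' @param annot data.frame with columns `probe_id`, `chrom`, `pos`, and
#'   logical flags `sex_chromosome`, `snp_affected`, `cross_reactive` (see
#'   [simulate_study()] for the full annotation layout).
#' @param det_threshold detection p-value threshold (default 0.01); a probe
#'   failing in any sample is removed.
#' @return list with `beta` (row-subset matrix) and `removed`, a named
#'   vector of per-rule removal counts (`detection`, `sex_chromosome`,
#'   `snp_affected`, `cross_reactive`; a probe is counted under every rule
#'   it fails) plus `total` unique probes removed.
#' @export
filter_probes <- function(beta, detection_p, annot, det_threshold = 0.01) {
  if (!identical(dim(beta), dim(detection_p)) ||
      !identical(rownames(beta), rownames(detection_p)) ||
      !identical(colnames(beta), colnames(detection_p))) {
    stop("beta and detection_p matrices are misaligned", call. = FALSE)
  }
  ids <- rownames(beta)
  an <- annot[match(ids, annot$probe_id), , drop = FALSE]
  if (anyNA(an$probe_id)) {
    stop("annotation missing for ", sum(is.na(an$probe_id)), " probe(s)",
         call. = FALSE)
  }
  fail_det <- apply(detection_p > det_threshold, 1L, any)
  fail_sex <- as.logical(an$sex_chromosome)
  fail_snp <- as.logical(an$snp_affected)
  fail_xr <- as.logical(an$cross_reactive)
  drop <- fail_det | fail_sex | fail_snp | fail_xr
  list(
    beta = beta[!drop, , drop = FALSE],
    removed = c(detection = sum(fail_det),
                sex_chromosome = sum(fail_sex),
                snp_affected = sum(fail_snp),
                cross_reactive = sum(fail_xr),
                total = sum(drop))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j>=i} m * p_(j) / j`, clipped at 1
#' and mapped back to input order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs are resolved rather than
#' propagated: two constant equal samples give `t = 0, p = 1`; two constant
#' unequal samples give `p = 0` with a warning.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("welch_t needs >= 2 values per sample",
                               call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (dm == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    warning("both samples constant with unequal means; p = 0")
    return(list(t = sign(dm) * Inf, df = nx + ny - 2, p = 0))
  }
  se2 <- vx / nx + vy / ny
  t <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## Method-of-moments fit of a scaled inverse-chi-squared prior to a set of
## sample variances s2 with common residual df. Returns list(d0, s0_squared);
## d0 = Inf when the variances are under-dispersed relative to chi-squared
## sampling noise alone (the limit is a common variance, estimated by the
## arithmetic mean). Trigamma inversion by monotone bisection.
estimate_variance_prior <- function(s2, df, tol = 1e-8, d0_cap = 1e6) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= tol) {
    return(list(d0 = Inf, s0_squared = mean(s2[ok])))
  }
  ## solve trigamma(d0/2) = evar; trigamma is strictly decreasing
  lo <- 1e-8; hi <- 2 * d0_cap
  if (trigamma(hi / 2) > evar) {
    return(list(d0 = Inf, s0_squared = mean(s2[ok])))
  }
  while (hi - lo > tol * (1 + hi)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > evar) lo <- mid else hi <- mid
  }
  d0 <- (lo + hi) / 2
  if (d0 >= d0_cap) return(list(d0 = Inf, s0_squared = mean(s2[ok])))
  s0 <- exp(mean(e) - log(d0 / 2) + digamma(d0 / 2))
  list(d0 = d0, s0_squared = s0)
}

#' Moderated F-test for two-group differential methylation
#'
#' Fits, per probe, ordinary least squares of the methylation value on a
#' case/control indicator, then moderates the residual variances with an
#' empirical-Bayes scaled inverse-chi-squared prior estimated from the
#' whole array by the method of moments on log variances (trigamma
#' inversion). The moderated statistic
#' \deqn{F_g = \frac{(\bar\beta_{case} - \bar\beta_{ctrl})^2}
#'   {\tilde s_g^2 (1/n_1 + 1/n_2)}, \quad
#'   \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' is referred to an F(1, d0 + dg) distribution. Without shrinkage this is
#' the textbook two-group ANOVA F.
#'
#' The sign convention throughout the package: `delta_beta = case - control`,
#' positive = hypermethylated in cases.
#'
#' @param beta probes x samples matrix (beta fractions, or any per-probe
#'   values); rows with missing values are dropped with a warning.
#' @param sheet sample sheet data.frame with `sample_id` and `group`
#'   (`"case"` / `"control"`); must cover all columns of `beta`, each group
#'   with >= 2 samples.
#' @param shrink apply empirical-Bayes variance moderation (default `TRUE`).
#' @param mvalues test on the logit2 scale `log2(beta/(1-beta))` (beta
#'   clipped to `[eps, 1-eps]`, `eps = 1e-6`) instead of the beta scale.
#'   Group means and `delta_beta` are always reported on the beta scale.
#' @param q_threshold significance threshold on the BH-adjusted q-value
#'   (default 0.05).
#' @return A `data.frame` (one row per tested probe): `probe_id`,
#'   `mean_beta_case`, `mean_beta_control`, `delta_beta`, `s2` (residual
#'   variance), `s2_moderated`, `F_statistic`, `p_value`, `q_value`,
#'   `significant`; with attributes `prior` (list `d0`, `s0_squared`) and
#'   `df_residual`.
#' @export
fit_moderated_f <- function(beta, sheet, shrink = TRUE, mvalues = FALSE,
                            q_threshold = 0.05) {
  grp <- sheet$group[match(colnames(beta), sheet$sample_id)]
  if (anyNA(grp)) stop("sample sheet does not cover all beta columns",
                       call. = FALSE)
  if (length(unique(grp)) < 2L) stop("need two groups to test",
                                     call. = FALSE)
  is_case <- grp == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group", call. = FALSE)

  complete <- !apply(is.na(beta), 1L, any)
  if (!all(complete)) {
    warning(sum(!complete), " probe(s) with missing values dropped")
    beta <- beta[complete, , drop = FALSE]
  }

  values <- beta
  if (mvalues) {
    eps <- 1e-6
    values <- pmin(pmax(beta, eps), 1 - eps)
    values <- log2(values / (1 - values))
  }

  m_case_b <- rowMeans(beta[, is_case, drop = FALSE])
  m_ctrl_b <- rowMeans(beta[, !is_case, drop = FALSE])
  m1 <- rowMeans(values[, is_case, drop = FALSE])
  m2 <- rowMeans(values[, !is_case, drop = FALSE])

  ## residual sum of squares about the two group means, df = n - 2
  rss <- rowSums((values[, is_case, drop = FALSE] - m1)^2) +
    rowSums((values[, !is_case, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- rss / dg

  if (shrink) {
    prior <- estimate_variance_prior(s2, dg)
    if (is.infinite(prior$d0)) {
      s2_mod <- rep(prior$s0_squared, length(s2))
      df2 <- Inf
    } else {
      s2_mod <- (prior$d0 * prior$s0_squared + dg * s2) / (prior$d0 + dg)
      df2 <- prior$d0 + dg
    }
  } else {
    prior <- list(d0 = 0, s0_squared = NA_real_)
    s2_mod <- s2
    df2 <- dg
  }

  num <- (m1 - m2)^2 / (1 / n1 + 1 / n2)
  f <- ifelse(s2_mod > 0, num / s2_mod, ifelse(num == 0, 0, Inf))
  f[num == 0] <- 0
  p <- ifelse(f == 0, 1, stats::pf(f, 1, df2, lower.tail = FALSE))
  q <- bh_adjust(p)

  out <- data.frame(
    probe_id = rownames(beta),
    mean_beta_case = m_case_b,
    mean_beta_control = m_ctrl_b,
    delta_beta = m_case_b - m_ctrl_b,
    s2 = s2,
    s2_moderated = s2_mod,
    F_statistic = f,
    p_value = p,
    q_value = q,
    significant = q < q_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "prior") <- prior
  attr(out, "df_residual") <- dg
  out
}

#' Read / write tabular inputs
#'
#' Thin TSV wrappers with the package's conventions: matrices are written
#' with a `probe_id` first column; sample sheets and tables round-trip
#' unchanged.
#'
#' @param path file path.
#' @return `read_beta_matrix`: numeric matrix with probe rownames;
#'   `read_tsv_table`: data.frame.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_beta_matrix
#' @param m matrix to write.
#' @param id_col name of the first (id) column.
#' @export
write_beta_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname read_beta_matrix
#' @export
read_tsv_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' @rdname read_beta_matrix
#' @param df data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
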