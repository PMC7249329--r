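#' Epigenetic clock application
#'
#' Applies a sparse linear methylation clock to one or more samples. The
#' linear score `intercept + sum(w_p * beta_p)` is mapped to years through
#' the standard piecewise log-linear age transform anchored at
#' `adult_age`:
#' \deqn{age = (1 + a) e^{score} - 1 \quad (score < 0), \qquad
#'       age = (1 + a)\,score + a \quad (score \ge 0)}
#' The two branches meet continuously at score 0 with value `adult_age`
#' and the transform is monotone increasing.
#'
#' @param beta probes x samples matrix (a single named vector is also
#'   accepted).
#' @param clock a clock model: list with `intercept` (numeric), `weights`
#'   (named numeric vector, probe id -> coefficient) and `adult_age`
#'   (default 20). See [read_clock()].
#' @param sheet optional sample sheet (`sample_id`, `age_years`, and
#'   optionally `passage`, `harvested`, `seeded`); when supplied,
#'   `delta_age` and the passage factor `rho` are filled in.
#' @param missing_policy what to do when clock probes are absent from
#'   `beta`: `"error"` (default, lists the missing probes) or
#'   `"mean_impute"` (substitute the cohort mean of the available clock
#'   probes... each missing probe is imputed as the mean beta of that
#'   probe across samples where present, or 0.5 if absent everywhere).
#' @return data.frame per sample: `sample_id`, `linear_score`, `dnam_age`,
#'   and (with `sheet`) `chronological_age`, `delta_age`, `rho`.
#' @export
apply_clock <- function(beta, clock, sheet = NULL,
                        missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  if (is.vector(beta)) beta <- matrix(beta, ncol = 1,
                                      dimnames = list(names(beta), "sample"))
  w <- clock$weights
  missing <- setdiff(names(w), rownames(beta))
  if (length(missing) > 0L) {
    if (missing_policy == "error") {
      stop("clock probes missing from beta matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) sprintf(" (and %d more)",
                                             length(missing) - 5L),
           call. = FALSE)
    }
    imp <- matrix(0.5, length(missing), ncol(beta),
                  dimnames = list(missing, colnames(beta)))
    beta <- rbind(beta, imp)
  }
  b <- beta[names(w), , drop = FALSE]
  score <- clock$intercept + as.vector(crossprod(b, w))
  age <- clock_transform(score, clock$adult_age %||% 20)
  out <- data.frame(sample_id = colnames(beta), linear_score = score,
                    dnam_age = age, stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    idx <- match(out$sample_id, sheet$sample_id)
    out$chronological_age <- sheet$age_years[idx]
    out$delta_age <- out$dnam_age - out$chronological_age
    if (all(c("passage", "harvested", "seeded") %in% names(sheet))) {
      out$rho <- passage_factor(sheet$passage[idx], sheet$harvested[idx],
                                sheet$seeded[idx])
    }
  }
  out
}

#' @rdname apply_clock
#' @param score linear clock score(s).
#' @param adult_age transform anchor in years (default 20).
#' @export
clock_transform <- function(score, adult_age = 20) {
  ifelse(score < 0,
         (1 + adult_age) * exp(score) - 1,
         (1 + adult_age) * score + adult_age)
}

#' @rdname apply_clock
#' @param age age(s) in years.
#' @export
clock_transform_inverse <- function(age, adult_age = 20) {
  ifelse(age < adult_age,
         log((age + 1) / (1 + adult_age)),
         (age - adult_age) / (1 + adult_age))
}

#' Passage factor (cumulative population doublings)
#'
#' `rho = passage * 3.32 * log10(harvested / seeded)`. Since
#' `3.32 ~ 1/log10(2)`, rho counts cumulative population doublings in
#' culture: one passage at a harvested/seeded ratio of 2 contributes one
#' doubling.
#'
#' @param passage passage number (>= 0).
#' @param harvested,seeded cell counts (> 0).
#' @return numeric rho, vectorized over the inputs.
#' @export
passage_factor <- function(passage, harvested, seeded) {
  if (any(harvested <= 0 | seeded <= 0, na.rm = TRUE)) {
    stop("cell counts must be positive", call. = FALSE)
  }
  if (any(passage < 0, na.rm = TRUE)) stop("passage must be >= 0",
                                           call. = FALSE)
  passage * 3.32 * log10(harvested / seeded)
}

#' Per-subgroup epigenetic age acceleration
#'
#' Median `delta_age = dnam_age - chronological_age` per subgroup; with
#' `adjust_rho = TRUE`, `delta_age` is first residualized against the
#' passage factor rho by least squares across all samples (an explicit
#' implementation choice for "passage correction"), and both raw and
#' adjusted medians are reported.
#'
#' @param estimates output of [apply_clock()] including `delta_age` (and
#'   `rho` when adjusting).
#' @param subgroups labels, one per row of `estimates`.
#' @param adjust_rho residualize against rho before the adjusted medians.
#' @return data.frame per subgroup: `subgroup`, `n`, `median_delta_age`
#'   and, when adjusted, `median_delta_age_rho_adjusted`.
#' @export
age_acceleration <- function(estimates, subgroups, adjust_rho = FALSE) {
  stopifnot(nrow(estimates) == length(subgroups))
  if (anyNA(estimates$delta_age)) {
    stop("chronological ages missing for some samples", call. = FALSE)
  }
  subgroups <- as.character(subgroups)
  if (any(!nzchar(subgroups) | is.na(subgroups))) {
    stop("every sample needs a subgroup label", call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(estimates)), subgroups)
  out <- data.frame(
    subgroup = names(split_idx),
    n = lengths(split_idx),
    median_delta_age = vapply(split_idx, function(i) {
      stats::median(estimates$delta_age[i])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (adjust_rho) {
    if (is.null(estimates$rho)) stop("rho column required for adjustment",
                                     call. = FALSE)
    fit <- stats::lm(delta_age ~ rho, data = estimates)
    adj <- stats::residuals(fit)
    out$median_delta_age_rho_adjusted <- vapply(split_idx, function(i) {
      stats::median(adj[i])
    }, numeric(1))
  }
  out
}

#' Read / write clock coefficient files
#'
#' A clock is stored as a TSV of `probe_id`, `weight` plus a side-car JSON
#' holding `intercept` and `adult_age`.
#'
#' @param weights_path TSV with columns `probe_id`, `weight`.
#' @param config_path JSON with fields `intercept`, `adult_age`.
#' @return a clock model list (`intercept`, `weights`, `adult_age`).
#' @export
read_clock <- function(weights_path, config_path) {
  wdf <- read_tsv_table(weights_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  w <- stats::setNames(wdf$weight, wdf$probe_id)
  if (anyDuplicated(names(w))) stop("duplicate clock probe ids",
                                    call. = FALSE)
  if (all(w == 0)) stop("clock has no non-zero weight", call. = FALSE)
  list(intercept = cfg$intercept, weights = w,
       adult_age = cfg$adult_age %||% 20)
}

#' @rdname read_clock
#' @param clock clock model list.
#' @export
write_clock <- function(clock, weights_path, config_path) {
  write_tsv_table(data.frame(probe_id = names(clock$weights),
                             weight = unname(clock$weights)),
                  weights_path)
  jsonlite::write_json(list(intercept = clock$intercept,
                            adult_age = clock$adult_age),
                       config_path, auto_unbox = TRUE, digits = NA)
  invisible(weights_path)
}
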