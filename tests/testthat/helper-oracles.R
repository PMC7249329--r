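# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (O(n*m) scans, full enumerations) so they can vouch
# for the package's faster implementations.

# pairwise O(n*m) overlap check under half-open coordinates
brute_overlaps <- function(queries, track) {
  vapply(seq_len(nrow(queries)), function(i) {
    any(track$chrom == queries$chrom[i] &
          track$start < queries$end[i] &
          track$end > queries$start[i])
  }, logical(1))
}

# pairwise minimum gap; NA when the query chromosome is absent
brute_nearest <- function(queries, track) {
  vapply(seq_len(nrow(queries)), function(i) {
    same <- track[track$chrom == queries$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(NA_real_)
    gaps <- pmax(0, pmax(same$start - queries$end[i],
                         queries$start[i] - same$end))
    min(gaps)
  }, numeric(1))
}

random_track <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# straightforward re-implementation of the bounded scan used as reference:
# walks each chromosome and re-derives every cluster boundary from scratch
reference_bounded_cluster <- function(pos_df, max_gap, max_width) {
  out <- integer(nrow(pos_df))
  cid <- 0L
  for (ch in sort(unique(pos_df$chrom))) {
    idx <- which(pos_df$chrom == ch)
    idx <- idx[order(pos_df$pos[idx])]
    members <- integer(0)
    for (i in idx) {
      open_new <- length(members) == 0L ||
        (pos_df$pos[i] - pos_df$pos[members[length(members)]]) > max_gap ||
        (pos_df$pos[i] - pos_df$pos[members[1L]]) > max_width
      if (open_new) {
        cid <- cid + 1L
        members <- integer(0)
      }
      members <- c(members, i)
      out[i] <- cid
    }
  }
  out
}

# exact two-sided Fisher p by full enumeration over tables with fixed margins
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Yates chi-squared by the hand formula, correction capped at |O - E|
hand_yates_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - e) - pmin(0.5, abs(tab - e)))^2 / e)
}

# exact two-sided rank-sum p by enumeration over all splits (no ties)
enumerate_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  combs <- utils::combn(n, nx)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# two-group ANOVA F via the textbook per-probe fit, used as the
# no-shrinkage oracle
anova_f_oracle <- function(v, is_case) {
  fit <- stats::aov(v ~ factor(is_case))
  s <- summary(fit)[[1]]
  c(F = s$`F value`[1], p = s$`Pr(>F)`[1])
}

skip_if_no_limma <- function() {
  testthat::skip_if_not_installed("limma")
}
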