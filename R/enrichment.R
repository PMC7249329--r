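#' Signed fold enrichment of a selection in an annotation track
#'
#' Core observed/expected statistic: the expected count of selected
#' features in the track is the track's share of the universe scaled to
#' the selection size,
#' `expected = n_selected * n_universe_in_track / n_universe`. Enrichment
#' is reported as a signed ratio: `observed/expected` when enriched,
#' `-expected/observed` when depleted (so a "-1.56-fold" depletion reads
#' directly), with `+1` at exact independence. Significance is Pearson's
#' chi-squared on the 2x2 table {selected, not} x {in track, not} with the
#' Yates continuity correction capped at `|O - E|` (so an exactly
#' independent table gives statistic 0, p = 1).
#'
#' @param selected logical vector over the probe/feature universe.
#' @param in_track logical vector, same length, membership in the track.
#' @param track_name optional label carried into the result.
#' @return one-row data.frame: `track_name`, `n_universe`,
#'   `n_universe_in_track`, `n_selected`, `observed`, `expected`,
#'   `signed_fold`, `fold` (plain ratio observed/expected), `test_name`,
#'   `statistic`, `p_value`.
#' @export
fold_enrichment <- function(selected, in_track, track_name = "track") {
  stopifnot(length(selected) == length(in_track))
  selected <- as.logical(selected); in_track <- as.logical(in_track)
  n <- length(selected)
  n_sel <- sum(selected)
  n_in <- sum(in_track)
  if (n_sel == 0L) stop("empty selection", call. = FALSE)
  if (n_in == 0L || n_in == n) {
    stop("degenerate track margin (no or all universe members in track)",
         call. = FALSE)
  }
  obs <- sum(selected & in_track)
  expected <- n_sel * n_in / n
  fold <- obs / expected
  signed <- if (obs >= expected) fold else -expected / obs

  tab <- matrix(c(obs, n_sel - obs, n_in - obs, n - n_sel - n_in + obs),
                nrow = 2L)
  e <- outer(rowSums(tab), colSums(tab)) / n
  corr <- pmin(0.5, abs(tab - e))
  stat <- sum((abs(tab - e) - corr)^2 / e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  data.frame(track_name = track_name, n_universe = n,
             n_universe_in_track = n_in, n_selected = n_sel,
             observed = obs, expected = expected,
             signed_fold = signed, fold = fold,
             test_name = "yates_chi2", statistic = stat, p_value = p,
             stringsAsFactors = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Reports the sample (cross-product) odds ratio `ad/bc` and the exact
#' two-sided p-value obtained by summing hypergeometric probabilities no
#' larger than that of the observed table (via [stats::fisher.test()]).
#' A zero off-diagonal product yields an infinite (or zero) odds ratio
#' with a finite p.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p = p)
}

#' Distribution of peaks across feature classes
#'
#' Counts, for each feature track, the peaks overlapping it by at least one
#' base. Categories are not mutually exclusive: a peak inside both a gene
#' and a LAD is counted in both. When `lad_tracks` names tracks present in
#' `feature_tracks`, an extra `non_LAD` category counts peaks overlapping
#' none of them.
#'
#' @param peaks a [genomic_track()] (non-empty).
#' @param feature_tracks named list of [genomic_track()] objects.
#' @param lad_tracks names (within `feature_tracks`) of the LAD tracks used
#'   to define the `non_LAD` complement category; `NULL` disables it.
#' @return data.frame with `feature`, `count`, `fraction`
#'   (`count / n_peaks`).
#' @export
peak_feature_distribution <- function(peaks, feature_tracks,
                                      lad_tracks = NULL) {
  if (nrow(peaks) == 0L) stop("empty peak set", call. = FALSE)
  counts <- vapply(feature_tracks, function(tr) sum(overlaps_any(peaks, tr)),
                   numeric(1))
  out <- data.frame(feature = names(feature_tracks), count = counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  lad_tracks <- intersect(lad_tracks, names(feature_tracks))
  if (length(lad_tracks) > 0L) {
    in_any_lad <- Reduce(`|`, lapply(feature_tracks[lad_tracks],
                                     function(tr) overlaps_any(peaks, tr)))
    out <- rbind(out, data.frame(feature = "non_LAD",
                                 count = sum(!in_any_lad)))
  }
  out$fraction <- out$count / nrow(peaks)
  out
}

#' Membership of probes in annotation tracks
#'
#' Computes, once, the boolean probe-by-track membership used by every
#' stratified comparison and enrichment figure, from the 1-based probe
#' coordinates against half-open tracks.
#'
#' @param annot probe annotation with `probe_id`, `chrom`, `pos`.
#' @param tracks named list of [genomic_track()] objects.
#' @return logical matrix, probes x tracks, rownames = probe ids.
#' @export
probe_track_membership <- function(annot, tracks) {
  q <- probe_intervals(annot$chrom, annot$pos, annot$probe_id)
  m <- vapply(tracks, function(tr) overlaps_any(q, tr),
              logical(nrow(annot)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(annot),
                                   dimnames = list(NULL, names(tracks)))
  rownames(m) <- annot$probe_id
  m
}

#' Stratified differential methylation (delta beta) by probe strata
#'
#' For each named probe stratum (e.g. all, non-LAD, lamin A LAD,
#' solo-WCGW PMD/HMD, per histone mark), reports the median per-probe
#' `delta_beta = mean(case) - mean(control)` and a Welch two-sample t-test
#' comparing the stratum's per-probe case means against its per-probe
#' control means (unpaired by default; `paired = TRUE` tests the per-probe
#' differences against zero via a one-sample t).
#'
#' @param beta probes x samples matrix.
#' @param sheet sample sheet with `sample_id`, `group` (`case`/`control`).
#' @param strata named list of logical vectors (or probe-id character
#'   vectors) defining each stratum over the rows of `beta`.
#' @param paired use a paired (per-probe difference) t-test instead of the
#'   unpaired Welch comparison of group-mean vectors.
#' @return data.frame with `stratum`, `n_probes`, `median_delta`, `t`,
#'   `df`, `p`.
#' @export
stratified_delta_beta <- function(beta, sheet, strata, paired = FALSE) {
  grp <- sheet$group[match(colnames(beta), sheet$sample_id)]
  is_case <- grp == "case"
  m_case <- rowMeans(beta[, is_case, drop = FALSE])
  m_ctrl <- rowMeans(beta[, !is_case, drop = FALSE])
  delta <- m_case - m_ctrl
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    if (is.character(sel)) sel <- rownames(beta) %in% sel
    if (sum(sel) == 0L) stop("empty stratum: ", nm, call. = FALSE)
    if (sum(sel) < 2L) stop("stratum '", nm, "' has a single probe; ",
                            "cannot test", call. = FALSE)
    if (paired) {
      tt <- stats::t.test(delta[sel])
      res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value)
    } else {
      res <- welch_t(m_case[sel], m_ctrl[sel])
    }
    data.frame(stratum = nm, n_probes = sum(sel),
               median_delta = stats::median(delta[sel]),
               t = res$t, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Enrichment suite over differential probes
#'
#' Convenience wrapper reproducing the track-by-direction enrichment
#' table: for each track, signed fold enrichment of all significant
#' probes, the hypermethylated subset and the hypomethylated subset.
#'
#' @param diff_table output of [fit_moderated_f()].
#' @param membership logical probes x tracks matrix from
#'   [probe_track_membership()], rows aligned by probe id.
#' @return data.frame of [fold_enrichment()] rows with an extra
#'   `direction` column in `{all, hyper, hypo}`.
#' @export
enrichment_suite <- function(diff_table, membership) {
  mem <- membership[match(diff_table$probe_id, rownames(membership)), ,
                    drop = FALSE]
  sig <- diff_table$significant
  sels <- list(all = sig,
               hyper = sig & diff_table$delta_beta > 0,
               hypo = sig & diff_table$delta_beta < 0)
  rows <- list()
  for (tr in colnames(mem)) {
    for (dir in names(sels)) {
      if (sum(sels[[dir]]) == 0L) next
      r <- fold_enrichment(sels[[dir]], mem[, tr], track_name = tr)
      r$direction <- dir
      rows[[paste(tr, dir)]] <- r
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
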