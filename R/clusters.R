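#' Bounded probe clustering
#'
#' Partitions CpG probes into clusters of nearby probes by a greedy
#' left-to-right scan per chromosome: a new cluster opens when the gap to
#' the previous probe exceeds `max_gap`, or when adding the probe would
#' push the cluster span (last position - first position) beyond
#' `max_width`. Singleton clusters are allowed; every probe belongs to
#' exactly one cluster.
#'
#' @param annot probe annotation data.frame with `probe_id`, `chrom`, `pos`
#'   (1-based CpG coordinate); `(chrom, pos)` must be unique.
#' @param max_gap maximum gap (bp) between consecutive member probes
#'   (default 500).
#' @param max_width maximum cluster span (bp), measured last minus first
#'   member position (default 1500).
#' @return data.frame with one row per probe: `cluster_id`, `probe_id`,
#'   `chrom`, `pos`; cluster ids are `"<chrom>:<start pos>"` of the first
#'   member.
#' @export
bounded_cluster <- function(annot, max_gap = 500, max_width = 1500) {
  key <- paste(annot$chrom, annot$pos)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos) in probe annotation",
                               call. = FALSE)
  ord <- order(annot$chrom, annot$pos)
  an <- annot[ord, , drop = FALSE]
  n <- nrow(an)
  if (n == 0L) {
    return(data.frame(cluster_id = character(), probe_id = character(),
                      chrom = character(), pos = numeric()))
  }
  cluster <- integer(n)
  cid <- 1L
  cluster[1L] <- cid
  start_pos <- an$pos[1L]
  for (i in seq_len(n)[-1L]) {
    new_chrom <- an$chrom[i] != an$chrom[i - 1L]
    gap <- an$pos[i] - an$pos[i - 1L]
    if (new_chrom || gap > max_gap || (an$pos[i] - start_pos) > max_width) {
      cid <- cid + 1L
      start_pos <- an$pos[i]
    }
    cluster[i] <- cid
  }
  first_pos <- stats::ave(an$pos, cluster, FUN = min)
  data.frame(
    cluster_id = paste0(an$chrom, ":", first_pos),
    probe_id = an$probe_id,
    chrom = an$chrom,
    pos = an$pos,
    stringsAsFactors = FALSE
  )
}

#' Summarize probe clusters over a beta matrix
#'
#' The per-sample cluster value is the unweighted mean beta of the member
#' probes (`summary = "median"` uses the member median instead);
#' variability is the across-sample standard deviation (n-1 denominator)
#' of the cluster values.
#'
#' @param clusters output of [bounded_cluster()].
#' @param beta probes x samples matrix; every cluster must have at least
#'   one member probe present.
#' @param summary per-cluster summary statistic, `"mean"` (default) or
#'   `"median"`.
#' @return list with `info` (data.frame `cluster_id`, `chrom`, `start`,
#'   `end`, `n_probes`, `variability`, sorted by coordinates) and `values`
#'   (clusters x samples matrix, rows aligned to `info`).
#' @export
summarize_clusters <- function(clusters, beta, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  cl <- clusters[clusters$probe_id %in% rownames(beta), , drop = FALSE]
  missing_cl <- setdiff(unique(clusters$cluster_id), unique(cl$cluster_id))
  if (length(missing_cl) > 0L) {
    stop("cluster(s) with no probe present in the beta matrix: ",
         paste(utils::head(missing_cl, 3L), collapse = ", "), call. = FALSE)
  }
  idx <- split(seq_len(nrow(cl)), cl$cluster_id)
  stat <- if (summary == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  vals <- t(vapply(idx, function(i) {
    stat(beta[cl$probe_id[i], , drop = FALSE])
  }, numeric(ncol(beta))))
  colnames(vals) <- colnames(beta)
  info <- data.frame(
    cluster_id = names(idx),
    chrom = vapply(idx, function(i) cl$chrom[i[1L]], character(1)),
    start = vapply(idx, function(i) min(cl$pos[i]), numeric(1)),
    end = vapply(idx, function(i) max(cl$pos[i]), numeric(1)),
    n_probes = lengths(idx),
    variability = apply(vals, 1L, stats::sd),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  ord <- order(info$chrom, info$start)
  list(info = info[ord, , drop = FALSE], values = vals[ord, , drop = FALSE])
}

#' Select the most variable probe clusters
#'
#' Top-k clusters by across-sample standard deviation, descending, with a
#' deterministic tie-break by `(chrom, start)`.
#'
#' @param summarized output of [summarize_clusters()].
#' @param k number of clusters to keep (default 5000); if `k` exceeds the
#'   number of clusters, all are returned with a warning.
#' @return list like `summarized`, rows ordered by decreasing variability.
#' @export
top_variable_clusters <- function(summarized, k = 5000) {
  info <- summarized$info
  if (k > nrow(info)) {
    warning("k = ", k, " exceeds ", nrow(info), " clusters; returning all")
    k <- nrow(info)
  }
  ord <- order(-info$variability, info$chrom, info$start)
  keep <- ord[seq_len(k)]
  list(info = info[keep, , drop = FALSE],
       values = summarized$values[keep, , drop = FALSE])
}
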