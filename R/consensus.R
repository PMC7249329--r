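#' Resampling consensus clustering of samples
#'
#' Repeatedly subsamples the columns (samples) of a feature matrix,
#' clusters each subsample by agglomerative hierarchical clustering, and
#' records for every sample pair how often it co-clusters among the
#' subsamples that contain both. The consensus matrix entry is
#' `(#co-clustered) / (#co-sampled)`. The final assignment for each K is a
#' hierarchical clustering of `1 - consensus` cut at K.
#'
#' The inner clustering is average-linkage agglomerative; the sample
#' distance is euclidean by default (`distance = "pearson"` switches to
#' `1 - Pearson correlation`, which is insensitive to additive
#' between-group shifts and therefore not the default). Both the distance
#' and linkage are configuration keys. The whole procedure is
#' deterministic given `seed`.
#'
#' @param features features x samples numeric matrix (no missing values).
#' @param max_k largest number of clusters considered (default 6).
#' @param reps number of resampling repetitions (default 1000).
#' @param p_item fraction of samples drawn (without replacement) per
#'   repetition (default 0.8).
#' @param p_feature fraction of features drawn per repetition (default 1).
#' @param seed integer master seed.
#' @param distance `"euclidean"` (default) or `"pearson"`
#'   (1 - correlation).
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return A `consensus_result` list with, per K in `2..max_k`:
#'   `consensus` (samples x samples matrix, symmetric, unit diagonal),
#'   `assignment` (integer labels), `cdf_area`; plus `sample_ids`,
#'   `leaf_order` (dendrogram order of the final clustering at each K) and
#'   the call parameters. Use [select_k()] to choose K.
#' @export
consensus_cluster <- function(features, max_k = 6, reps = 1000,
                              p_item = 0.8, p_feature = 1.0, seed = 1,
                              distance = c("euclidean", "pearson"),
                              linkage = "average") {
  distance <- match.arg(distance)
  n <- ncol(features)
  m <- nrow(features)
  if (n < max_k + 1L) stop("need at least max_k + 1 samples", call. = FALSE)
  if (anyNA(features)) stop("missing values in feature matrix", call. = FALSE)
  n_sub <- ceiling(p_item * n)
  if (n_sub < max_k) stop("p_item * n < max_k: subsamples too small",
                          call. = FALSE)
  m_sub <- ceiling(p_feature * m)
  ids <- colnames(features) %||% paste0("S", seq_len(n))

  sample_dist <- function(x) {
    if (distance == "pearson") stats::as.dist(1 - stats::cor(x))
    else stats::dist(t(x))
  }

  ks <- 2:max_k
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(ks, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(ks)

  set.seed(as.integer(seed %% .Machine$integer.max))
  for (r in seq_len(reps)) {
    samp <- sort(sample.int(n, n_sub))
    feat <- if (m_sub < m) sort(sample.int(m, m_sub)) else seq_len(m)
    co_sampled[samp, samp] <- co_sampled[samp, samp] + 1
    hc <- stats::hclust(sample_dist(features[feat, samp, drop = FALSE]),
                        method = linkage)
    for (ki in seq_along(ks)) {
      lab <- stats::cutree(hc, k = ks[ki])
      same <- outer(lab, lab, "==") * 1
      co_clustered[[ki]][samp, samp] <- co_clustered[[ki]][samp, samp] + same
    }
  }

  full_dist <- as.matrix(sample_dist(features))

  per_k <- lapply(seq_along(ks), function(ki) {
    cons <- ifelse(co_sampled > 0, co_clustered[[ki]] / co_sampled, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    hc <- stats::hclust(stats::as.dist(1 - cons), method = linkage)
    assignment <- stats::cutree(hc, k = ks[ki])
    v <- cons[upper.tri(cons)]
    ## area under the empirical CDF of consensus entries on [0, 1]
    cdf_area <- 1 - mean(v)
    list(consensus = cons, assignment = assignment,
         cdf_area = cdf_area, leaf_order = hc$order)
  })
  names(per_k) <- as.character(ks)

  structure(list(per_k = per_k, sample_ids = ids, max_k = max_k,
                 reps = reps, p_item = p_item, p_feature = p_feature,
                 seed = seed, distance = distance, linkage = linkage,
                 dist_matrix = full_dist),
            class = "consensus_result")
}

#' Choose the number of clusters from a consensus result
#'
#' Applies the consensus-CDF relative delta-area criterion, hardened with
#' the proportion of ambiguous clustering (PAC): scanning K upward from 3,
#' K is accepted while the relative increase in area under the consensus
#' CDF, `(A(K) - A(K-1)) / A(K-1)`, exceeds `threshold` AND the consensus
#' at K remains crisp (PAC, the fraction of off-diagonal consensus entries
#' falling strictly inside `pac_range`, at most `pac_crisp`) AND the
#' K-partition is separated in feature space (a Dunn-type index: for every
#' pair of clusters, the mean between-cluster distance divided by the mean
#' within-cluster distance of that pair must exceed `sep_min`). The chosen
#' K is the last accepted value before the first failure (K = 2 when the
#' step to K = 3 already fails).
#'
#' The PAC condition distinguishes a stable split (entries near 0 or 1)
#' from the fragmentation of noise (entries spread out); without it the
#' raw delta-area always favours the largest K. The separation condition
#' rejects splits that are stable merely because the realized noise of a
#' fixed feature matrix is itself stable under sample resampling: such
#' splits have between/within distance ratios of ~1.0, whereas genuine
#' subgroups sit well above it. When the scan stops at K = 2 and even the
#' two-cluster consensus is ambiguous (PAC at K = 2 above
#' `pac_no_structure`), there is no consensus structure and the K = 2
#' default is accompanied by a warning.
#'
#' @param result a `consensus_result` from [consensus_cluster()].
#' @param threshold relative delta-area threshold (default 0.05).
#' @param pac_range interval defining "ambiguous" consensus entries
#'   (default `c(0.1, 0.9)`).
#' @param pac_crisp largest PAC at which a K is still considered stable
#'   (default 0.05).
#' @param pac_no_structure PAC at K = 2 above which a defaulted K = 2 is
#'   reported as "no structure" (default 0.25).
#' @param sep_min minimum between/within distance ratio for the partition
#'   at K to count as separated (default 1.15).
#' @return list with `chosen_k`, `assignment` (labels at the chosen K),
#'   `delta_area` (named vector: absolute area at K = 2, then relative
#'   increases for K >= 3), `pac` and `separation` (named vectors over K).
#' @export
select_k <- function(result, threshold = 0.05, pac_range = c(0.1, 0.9),
                     pac_crisp = 0.05, pac_no_structure = 0.25,
                     sep_min = 1.15) {
  ks <- 2:result$max_k
  areas <- vapply(result$per_k, function(x) x$cdf_area, numeric(1))
  pac <- vapply(result$per_k, function(x) {
    v <- x$consensus[upper.tri(x$consensus)]
    mean(v > pac_range[1] & v < pac_range[2])
  }, numeric(1))
  names(pac) <- as.character(ks)
  rel <- diff(areas) / utils::head(areas, -1L)
  names(rel) <- as.character(ks[-1L])
  sep <- vapply(result$per_k, function(x) {
    partition_separation(result$dist_matrix, x$assignment)
  }, numeric(1))
  names(sep) <- as.character(ks)

  chosen <- 2L
  for (ki in seq_along(rel)) {
    k <- ks[ki + 1L]
    if (is.finite(rel[ki]) && rel[ki] > threshold &&
        pac[as.character(k)] <= pac_crisp &&
        sep[as.character(k)] > sep_min) chosen <- k
    else break
  }
  if (chosen == 2L && pac[["2"]] > pac_no_structure) {
    warning("no consensus structure detected; chosen_k = 2 by default")
  }
  list(chosen_k = chosen,
       assignment = result$per_k[[as.character(chosen)]]$assignment,
       delta_area = c("2" = unname(areas[1L]), rel),
       pac = pac, separation = sep)
}

## Dunn-type separation of a partition: the minimum over cluster pairs of
## mean(between distances) / mean(within distances of the pair's members);
## pairs of two singletons contribute Inf (no within scale to compare).
partition_separation <- function(D, labels) {
  cl <- unique(labels)
  if (length(cl) < 2L) return(Inf)
  ratios <- utils::combn(cl, 2L, FUN = function(pr) {
    i <- which(labels == pr[1]); j <- which(labels == pr[2])
    wi <- D[i, i, drop = FALSE][upper.tri(matrix(0, length(i), length(i)))]
    wj <- D[j, j, drop = FALSE][upper.tri(matrix(0, length(j), length(j)))]
    w <- c(wi, wj)
    if (length(w) == 0L) return(Inf)
    mean(D[i, j]) / mean(w)
  })
  min(ratios)
}

#' PCA embedding of samples
#'
#' Column-centered singular value decomposition of the samples-in-rows
#' data; component signs are fixed so the largest-magnitude loading of
#' each component is positive, making the embedding deterministic.
#'
#' @param features features x samples matrix.
#' @param n_components number of components (default
#'   `min(dim) - 1` capped at 10).
#' @return list with `coordinates` (samples x components), `loadings`
#'   (features x components, orthonormal columns) and
#'   `explained_variance` (fractions, sum <= 1).
#' @export
pca_embed <- function(features, n_components = NULL) {
  x <- t(features)                      # samples x features
  if (all(apply(x, 2L, stats::var) == 0)) {
    stop("zero-variance data: PCA undefined", call. = FALSE)
  }
  k_max <- min(nrow(x) - 1L, ncol(x))
  n_components <- n_components %||% min(k_max, 10L)
  if (n_components > k_max) stop("n_components exceeds matrix rank bound",
                                 call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE]
  coords <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, loadings = load,
       explained_variance = ev[keep])
}

#' Adjusted Rand index between two labelings
#'
#' Used to compare recovered subtypes against planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
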