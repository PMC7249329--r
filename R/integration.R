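#' Assign genomic features to genes
#'
#' Maps each feature interval to every gene whose body it overlaps by at
#' least one base; with `mode = "promoter"`, the target regions are
#' `TSS +/- promoter_window` instead. Features overlapping no gene map to
#' an empty set.
#'
#' @param features a [genomic_track()] (e.g. differential peaks).
#' @param genes gene annotation data.frame: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open body), `tss` (0-based position), `strand`.
#' @param mode `"body"` (default) or `"promoter"`.
#' @param promoter_window half-width of the promoter window in bp
#'   (default 2000).
#' @return named list, one character vector of gene ids per feature (named
#'   by the feature `name` column when present, else by index).
#' @export
assign_features_to_genes <- function(features, genes,
                                     mode = c("body", "promoter"),
                                     promoter_window = 2000) {
  mode <- match.arg(mode)
  targets <- if (mode == "body") {
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end)
  } else {
    data.frame(chrom = genes$chrom,
               start = pmax(0, genes$tss - promoter_window),
               end = genes$tss + promoter_window)
  }
  feat_names <- if (!is.null(features$name) && !anyNA(features$name) &&
                    !anyDuplicated(features$name)) features$name
                else as.character(seq_len(nrow(features)))
  out <- stats::setNames(rep(list(character(0)), nrow(features)),
                         feat_names)
  if (nrow(features) == 0L || nrow(genes) == 0L) return(out)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(features), as_granges(targets))
  )
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) out[[i]] <- sort(unique(genes$gene_id[sh[qh == i]]))
  out
}

#' Multi-omic overlap of differential gene sets
#'
#' Pairwise and triple intersections of the differentially expressed,
#' differentially accessible and differentially methylated gene sets
#' (Venn structure), with counts and sorted member lists.
#'
#' @param de_genes,accessible_genes,methylated_genes character vectors of
#'   gene ids from a shared namespace.
#' @return list with `counts` (named numeric vector: set sizes, pairwise
#'   and triple intersections) and `members` (sorted id vectors for each
#'   intersection).
#' @export
multiomic_overlap <- function(de_genes, accessible_genes, methylated_genes) {
  d <- unique(de_genes); a <- unique(accessible_genes)
  m <- unique(methylated_genes)
  de_acc <- sort(intersect(d, a))
  de_meth <- sort(intersect(d, m))
  acc_meth <- sort(intersect(a, m))
  triple <- sort(intersect(de_acc, m))
  list(
    counts = c(de = length(d), accessible = length(a),
               methylated = length(m),
               de_and_accessible = length(de_acc),
               de_and_methylated = length(de_meth),
               accessible_and_methylated = length(acc_meth),
               de_and_accessible_and_methylated = length(triple)),
    members = list(de_and_accessible = de_acc,
                   de_and_methylated = de_meth,
                   accessible_and_methylated = acc_meth,
                   de_and_accessible_and_methylated = triple)
  )
}

#' Distance-to-nearest-LAD test for gene sets
#'
#' For each gene, the distance from its body (or TSS with
#' `from = "tss"`) to the nearest interval of the LAD union track (0 for
#' genes inside a LAD; genes on chromosomes absent from the track are
#' excluded). Per set, the median distance; between every pair of sets, a
#' two-sided Wilcoxon rank-sum p-value with continuity correction.
#'
#' @param gene_sets named list of gene-id vectors (each non-empty and
#'   resolvable in `genes`).
#' @param genes gene annotation (see [assign_features_to_genes()]).
#' @param lad_union a [genomic_track()], typically
#'   `track_union(laminA, laminB)`.
#' @param from measure from `"body"` (default) or `"tss"`.
#' @return list with `medians` (data.frame `set`, `n_genes`,
#'   `median_distance`), `pairwise_p` (matrix), and `distances` (named
#'   list of per-gene distances).
#' @export
geneset_lad_distance_test <- function(gene_sets, genes, lad_union,
                                      from = c("body", "tss")) {
  from <- match.arg(from)
  if (nrow(lad_union) == 0L) stop("empty LAD track", call. = FALSE)
  dists <- lapply(names(gene_sets), function(nm) {
    ids <- gene_sets[[nm]]
    if (length(ids) == 0L) stop("empty gene set: ", nm, call. = FALSE)
    idx <- match(ids, genes$gene_id)
    if (anyNA(idx)) stop("unresolvable gene id(s) in set ", nm,
                         call. = FALSE)
    q <- if (from == "body") {
      data.frame(chrom = genes$chrom[idx], start = genes$start[idx],
                 end = genes$end[idx])
    } else {
      data.frame(chrom = genes$chrom[idx], start = genes$tss[idx],
                 end = genes$tss[idx] + 1)
    }
    d <- nearest_distance(q, lad_union)
    d[!is.na(d)]
  })
  names(dists) <- names(gene_sets)
  medians <- data.frame(
    set = names(dists),
    n_genes = lengths(dists),
    median_distance = vapply(dists, stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  k <- length(dists)
  pw <- matrix(NA_real_, k, k, dimnames = list(names(dists), names(dists)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pw[i, j] <- if (i == j) 1 else
        wilcoxon_rank_sum(dists[[i]], dists[[j]])$p
    }
  }
  list(medians = medians, pairwise_p = pw, distances = dists)
}

#' Cross-study expression correlation
#'
#' Pearson correlation of per-gene mean expression between two studies,
#' after intersecting gene ids and (by default) a `log2(x + 1)` transform
#' appropriate for FPKM-scale values.
#'
#' @param x,y named numeric vectors of per-gene mean expression.
#' @param log_transform apply `log2(value + 1)` before correlating
#'   (default `TRUE`).
#' @return list with `pearson_r`, `r_squared`, `n_genes`.
#' @export
expression_correlation <- function(x, y, log_transform = TRUE) {
  shared <- intersect(names(x), names(y))
  xv <- x[shared]; yv <- y[shared]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("fewer than 3 shared genes", call. = FALSE)
  if (log_transform) {
    xv <- log2(xv + 1); yv <- log2(yv + 1)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in expression vector", call. = FALSE)
  }
  r <- stats::cor(xv, yv)
  list(pearson_r = r, r_squared = r^2, n_genes = length(xv))
}

#' Top probes by absolute group difference
#'
#' Ranks probes by `|mean_a - mean_b|`, descending, with a deterministic
#' tie-break by probe id; used to extract the strongest methylation
#' differences between two cohorts.
#'
#' @param mean_beta_a,mean_beta_b named numeric vectors over a shared,
#'   detection-filtered probe universe.
#' @param k number of probes to return (default 1000).
#' @return data.frame `probe_id`, `abs_difference`, ranked.
#' @export
top_differential_probes <- function(mean_beta_a, mean_beta_b, k = 1000) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  shared <- intersect(names(mean_beta_a), names(mean_beta_b))
  d <- abs(mean_beta_a[shared] - mean_beta_b[shared])
  if (k > length(d)) {
    warning("k exceeds the probe universe; returning all ", length(d),
            " probes")
    k <- length(d)
  }
  ord <- order(-d, names(d))
  data.frame(probe_id = names(d)[ord][seq_len(k)],
             abs_difference = unname(d[ord])[seq_len(k)],
             stringsAsFactors = FALSE)
}
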