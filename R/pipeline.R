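#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: input
#' file paths (defaulting to the layout written by [simulate_study()]),
#' the parameter block of every stage, the output directory and the seed.
#' Every referenced path must exist at validation time; unknown parameter
#' keys are rejected.
#'
#' @param input_dir directory holding the input files (layout of
#'   [simulate_study()]).
#' @param output_dir directory for stage outputs and the summary.
#' @param seed integer seed (used by the consensus-clustering stage).
#' @param ... parameter overrides: `det_threshold` (0.01), `q_threshold`
#'   (0.05), `shrink` (TRUE), `mvalues` (FALSE), `max_gap` (500),
#'   `max_width` (1500), `top_k_clusters` (5000), `max_k` (6), `reps`
#'   (1000), `p_item` (0.8), `p_feature` (1), `promoter_window` (2000),
#'   `select_k_threshold` (0.05).
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1, ...) {
  params <- list(det_threshold = 0.01, q_threshold = 0.05, shrink = TRUE,
                 mvalues = FALSE, max_gap = 500, max_width = 1500,
                 top_k_clusters = 5000, max_k = 6, reps = 1000,
                 p_item = 0.8, p_feature = 1, promoter_window = 2000,
                 select_k_threshold = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(params))
  if (length(unknown) > 0L) {
    stop("unknown pipeline parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params[names(over)] <- over
  paths <- list(
    beta = file.path(input_dir, "beta.tsv"),
    detection_p = file.path(input_dir, "detection_p.tsv"),
    annot = file.path(input_dir, "probe_annotation.tsv"),
    sheet = file.path(input_dir, "sample_sheet.tsv"),
    genes = file.path(input_dir, "genes.tsv"),
    peaks = file.path(input_dir, "diff_peaks.tsv"),
    expression = file.path(input_dir, "expression.tsv"),
    accessible_genes = file.path(input_dir, "accessible_genes.txt"),
    methylated_genes = file.path(input_dir, "methylated_genes.txt"),
    clock_weights = file.path(input_dir, "clock_weights.tsv"),
    clock_config = file.path(input_dir, "clock_config.json"),
    clock_beta = file.path(input_dir, "clock_beta.tsv"),
    laminA = file.path(input_dir, "tracks", "laminA_LAD.bed"),
    laminB = file.path(input_dir, "tracks", "laminB_LAD.bed")
  )
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing)) {
    stop("missing input file(s): ",
         paste(unlist(paths[missing]), collapse = ", "), call. = FALSE)
  }
  track_dir <- file.path(input_dir, "tracks")
  histone_files <- setdiff(list.files(track_dir, pattern = "\\.bed$"),
                           c("laminA_LAD.bed", "laminB_LAD.bed",
                             "inter_laminA.bed", "PMD.bed", "HMD.bed"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 seed = seed, paths = paths,
                 histone_files = file.path(track_dir, histone_files),
                 params = params),
            class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: probe filtering; moderated-F differential
#' methylation; bounded probe clustering and selection of the most
#' variable clusters; consensus subtyping (with K selection and PCA);
#' track membership, stratified delta-beta and the signed fold-enrichment
#' suite; peak distribution across feature classes and peak LAD
#' enrichment; epigenetic-age estimation with the passage factor and
#' per-subtype age acceleration; and multi-omic integration (gene
#' overlaps and the distance-to-nearest-LAD test). Writes per-stage TSVs
#' and a machine-readable `summary.json` to the output directory; the
#' summary is a pure function of (inputs, parameters, seed), so reruns
#' are byte-identical. A log of the settings in force is written to
#' `run_log.txt`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(config) {
  p <- config$params
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("ladmeth %s",
                         as.character(utils::packageVersion("ladmeth"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("params: %s",
                         paste(names(p), unlist(p), sep = "=",
                               collapse = " ")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name,
                                      conditionMessage(e))),
                 file.path(out_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- load inputs ----------------------------------------------------
  beta <- stage("load", read_beta_matrix(config$paths$beta))
  det_p <- read_beta_matrix(config$paths$detection_p)
  annot <- read_tsv_table(config$paths$annot)
  sheet <- read_tsv_table(config$paths$sheet)
  laminA <- read_bed(config$paths$laminA, "laminA_LAD")
  laminB <- read_bed(config$paths$laminB, "laminB_LAD")
  histone <- lapply(config$histone_files, function(f) {
    read_bed(f, sub("\\.bed$", "", basename(f)))
  })
  names(histone) <- sub("\\.bed$", "", basename(config$histone_files))

  ## -- probe filtering ------------------------------------------------
  filt <- stage("filter", filter_probes(beta, det_p, annot,
                                        det_threshold = p$det_threshold))
  beta_f <- filt$beta

  ## -- differential methylation ---------------------------------------
  diff_table <- stage("diffmeth",
                      fit_moderated_f(beta_f, sheet, shrink = p$shrink,
                                      mvalues = p$mvalues,
                                      q_threshold = p$q_threshold))
  write_tsv_table(diff_table, file.path(out_dir, "differential_probes.tsv"))

  ## -- probe clusters --------------------------------------------------
  annot_f <- annot[annot$probe_id %in% rownames(beta_f), , drop = FALSE]
  clusters <- stage("clusters", bounded_cluster(annot_f,
                                                max_gap = p$max_gap,
                                                max_width = p$max_width))
  summarized <- summarize_clusters(clusters, beta_f)
  top <- top_variable_clusters(summarized, k = min(p$top_k_clusters,
                                                   nrow(summarized$info)))
  write_tsv_table(top$info, file.path(out_dir, "top_clusters.tsv"))

  ## -- consensus subtyping ---------------------------------------------
  cons <- stage("subtype",
                consensus_cluster(top$values, max_k = p$max_k,
                                  reps = p$reps, p_item = p$p_item,
                                  p_feature = p$p_feature,
                                  seed = config$seed))
  sel <- select_k(cons, threshold = p$select_k_threshold)
  pca <- pca_embed(top$values, n_components = 2)
  assign_df <- data.frame(sample_id = cons$sample_ids,
                          subtype = sel$assignment,
                          PC1 = pca$coordinates[, 1],
                          PC2 = pca$coordinates[, 2])
  write_tsv_table(assign_df, file.path(out_dir, "subtypes.tsv"))

  ## -- stratified delta beta + enrichment suite ------------------------
  tracks <- c(list(laminA_LAD = laminA, laminB_LAD = laminB), histone)
  membership <- stage("enrich", probe_track_membership(annot_f, tracks))
  an_idx <- match(rownames(beta_f), annot_f$probe_id)
  strata <- list(
    all = rep(TRUE, nrow(beta_f)),
    non_LAD = !membership[, "laminA_LAD"] & !membership[, "laminB_LAD"],
    laminA_LAD = membership[, "laminA_LAD"],
    soloWCGW_PMD = annot_f$solo_wcgw[an_idx] & annot_f$in_pmd[an_idx],
    soloWCGW_HMD = annot_f$solo_wcgw[an_idx] & annot_f$in_hmd[an_idx]
  )
  for (mk in names(histone)) strata[[mk]] <- membership[, mk]
  strata <- strata[vapply(strata, sum, numeric(1)) >= 2]
  strat <- stratified_delta_beta(beta_f, sheet, strata)
  write_tsv_table(strat, file.path(out_dir, "stratified_delta_beta.tsv"))
  enr <- enrichment_suite(diff_table, membership)
  write_tsv_table(enr, file.path(out_dir, "probe_enrichment.tsv"))

  ## -- peaks -----------------------------------------------------------
  peaks_df <- read_tsv_table(config$paths$peaks)
  genes <- read_tsv_table(config$paths$genes)
  sig_peaks <- peaks_df[peaks_df$significant, , drop = FALSE]
  peak_track <- genomic_track(sig_peaks$chrom, sig_peaks$start,
                              sig_peaks$end, name = sig_peaks$name,
                              track_name = "diff_peaks")
  gene_track <- genomic_track(genes$chrom, genes$start, genes$end,
                              name = genes$gene_id, track_name = "genes")
  feat_tracks <- c(list(genes = gene_track, laminA_LAD = laminA,
                        laminB_LAD = laminB), histone)
  peak_dist <- stage("peaks",
                     peak_feature_distribution(peak_track, feat_tracks,
                                               lad_tracks = c("laminA_LAD",
                                                              "laminB_LAD")))
  write_tsv_table(peak_dist, file.path(out_dir, "peak_distribution.tsv"))
  all_peaks_in_lad <- overlaps_any(peaks_df, laminA)
  peak_enr <- lapply(c(gained = "gained", lost = "lost"), function(dir) {
    sel <- peaks_df$direction == dir
    if (sum(sel) == 0L) return(NULL)
    fold_enrichment(sel, all_peaks_in_lad,
                    track_name = paste0("laminA_LAD_", dir))
  })
  peak_enr <- do.call(rbind, peak_enr)
  write_tsv_table(peak_enr, file.path(out_dir, "peak_lad_enrichment.tsv"))

  ## -- epigenetic age ---------------------------------------------------
  clock <- stage("age", read_clock(config$paths$clock_weights,
                                   config$paths$clock_config))
  clock_beta <- read_beta_matrix(config$paths$clock_beta)
  ages <- apply_clock(clock_beta, clock, sheet = sheet)
  subgroup <- sheet$subgroup[match(ages$sample_id, sheet$sample_id)]
  accel <- age_acceleration(ages, subgroup, adjust_rho = TRUE)
  write_tsv_table(ages, file.path(out_dir, "age_estimates.tsv"))
  write_tsv_table(accel, file.path(out_dir, "age_acceleration.tsv"))

  ## -- integration ------------------------------------------------------
  expr <- read_tsv_table(config$paths$expression)
  accessible <- readLines(config$paths$accessible_genes)
  methylated <- readLines(config$paths$methylated_genes)
  de_genes <- expr$gene_id[expr$significant]
  overlap <- stage("integrate",
                   multiomic_overlap(de_genes, accessible, methylated))
  lad_union <- track_union(laminA, laminB, track_name = "LAD_union")
  gene_sets <- list(
    de_and_accessible = overlap$members$de_and_accessible,
    de_only = setdiff(de_genes, accessible),
    background = setdiff(genes$gene_id, de_genes)
  )
  gene_sets <- gene_sets[lengths(gene_sets) > 0]
  lad_dist <- geneset_lad_distance_test(gene_sets, genes, lad_union)
  write_tsv_table(lad_dist$medians, file.path(out_dir,
                                              "lad_distance_medians.tsv"))

  ## -- summary ----------------------------------------------------------
  pick <- function(df, track, dir) {
    r <- df[df$track_name == track & df$direction == dir, ]
    if (nrow(r) == 1L) r$signed_fold else NA_real_
  }
  summary <- list(
    schema_version = 1L,
    seed = config$seed,
    n_probes_input = nrow(beta),
    n_probes_removed = unname(filt$removed[["total"]]),
    n_probes_tested = nrow(diff_table),
    n_differential_probes = sum(diff_table$significant),
    n_hypermethylated = sum(diff_table$significant &
                              diff_table$delta_beta > 0),
    n_hypomethylated = sum(diff_table$significant &
                             diff_table$delta_beta < 0),
    n_probe_clusters = nrow(summarized$info),
    chosen_k = sel$chosen_k,
    subtype_sizes = as.list(table(sel$assignment)),
    pc1_explained_variance = pca$explained_variance[1],
    median_delta_beta_laminA = strat$median_delta[strat$stratum ==
                                                    "laminA_LAD"],
    laminA_fold_all = pick(enr, "laminA_LAD", "all"),
    laminA_fold_hyper = pick(enr, "laminA_LAD", "hyper"),
    laminA_fold_hypo = pick(enr, "laminA_LAD", "hypo"),
    n_significant_peaks = nrow(sig_peaks),
    n_gained_peaks = sum(peaks_df$direction == "gained"),
    n_lost_peaks = sum(peaks_df$direction == "lost"),
    peak_lad_fold_gained = peak_enr$signed_fold[
      peak_enr$track_name == "laminA_LAD_gained"],
    peak_lad_fold_lost = peak_enr$signed_fold[
      peak_enr$track_name == "laminA_LAD_lost"],
    median_delta_age = stats::setNames(as.list(accel$median_delta_age),
                                       accel$subgroup),
    n_de_genes = length(de_genes),
    n_de_up = sum(expr$significant & expr$log2_fold_change > 0),
    n_de_down = sum(expr$significant & expr$log2_fold_change < 0),
    overlap_counts = as.list(overlap$counts),
    lad_distance_medians = stats::setNames(
      as.list(lad_dist$medians$median_distance), lad_dist$medians$set),
    lad_distance_p_de_accessible_vs_background =
      if (all(c("de_and_accessible", "background") %in%
              rownames(lad_dist$pairwise_p)))
        lad_dist$pairwise_p["de_and_accessible", "background"]
      else NA_real_
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "status: ok"),
             file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
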