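#' Simulation configuration
#'
#' Returns the default configuration of the synthetic-data generator,
#' optionally overridden by named arguments. The defaults emulate the
#' structure of the fibroblast study design the package targets: 6 control
#' and 9 case samples, with the cases split into a subgroup carrying only
#' LAD-restricted hypermethylation (`case1`, n = 5) and an age-accelerated
#' subgroup carrying an additional global shift toward partial methylation
#' (`case2`, n = 4); LAD-enriched hypermethylation of `+0.10` beta; 545
#' differential accessibility peaks (397 gained / 148 lost) placed with
#' 2.6- and 3.3-fold lamin A LAD enrichment; 343 differentially expressed
#' genes (160 up / 183 down) whose accessibility-coupled subset is placed
#' LAD-proximal; and planted epigenetic-age offsets of +9.73 / -1.51 years
#' in the two case subgroups.
#'
#' Beta-value noise is drawn from Beta distributions parameterized by
#' (mean, concentration) per region class; the default concentrations give
#' a per-probe standard deviation of about 0.03.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list (class `sim_config`).
#' @export
simulation_config <- function(...) {
  cfg <- list(
    ## genome layout
    n_chromosomes = 4L,
    chrom_length = 2e7,
    sex_chrom_length = 5e6,
    lad_fraction = 0.2,
    lad_mean_length = 2.5e5,
    pmd_given_lad = 0.8,
    pmd_given_inter = 0.05,
    ## probes
    n_probes = 20000L,
    sex_probe_fraction = 0.03,
    lad_probe_density = 0.5,     # probe density in LADs relative to outside
    island_fraction = 0.10,
    solo_wcgw_fraction = 0.20,
    snp_fraction = 0.01,
    cross_reactive_fraction = 0.01,
    ## beta noise: class means and concentrations
    mean_island = 0.10, mean_pmd = 0.60, mean_hmd = 0.85,
    conc_island = 100, conc_pmd = 250, conc_hmd = 150,
    clip = c(0.02, 0.98),
    ## sample design
    n_control = 6L, n_case1 = 5L, n_case2 = 4L,
    ## planted methylation effects
    lad_delta_beta = 0.10,
    lad_effect_fraction = 1.0,   # fraction of lamin A LAD probes affected
    lad_effect_n = NULL,         # absolute override of the affected count
    pm_shift_strength = 0.25,    # case2 shrinkage of means toward 0.5
    ## detection p-values
    det_fail_fraction = 0.002,
    ## histone marks: (n intervals, width, P(inside lamin A LAD))
    histone_marks = list(
      H3K4me1 = list(n = 400L, width = 5000, p_lad = 0.60),
      H3K4me2 = list(n = 300L, width = 3000, p_lad = 0.30),
      H3K4me3 = list(n = 300L, width = 2000, p_lad = 0.10),
      H3K27ac = list(n = 300L, width = 3000, p_lad = 0.15),
      H3K36me3 = list(n = 300L, width = 8000, p_lad = 0.15),
      H3K9me3 = list(n = 400L, width = 10000, p_lad = 0.65),
      H3K27me3 = list(n = 300L, width = 8000, p_lad = 0.40)
    ),
    ## genes
    n_genes = 2000L,
    gene_length_range = c(5e3, 5e4),
    gene_p_lad = 0.10,
    ## differential peaks
    n_background_peaks = 10000L,
    n_gained_peaks = 397L,
    n_lost_peaks = 148L,
    peak_width = 500,
    lad_peak_enrichment_gained = 2.6,
    lad_peak_enrichment_lost = 3.3,
    ## differential expression and multi-omic structure
    n_de_up = 160L, n_de_down = 183L,
    n_accessible_genes = 300L, n_methylated_genes = 250L,
    n_de_accessible = 21L, n_de_methylated = 14L, n_triple = 3L,
    lad_proximal_max = 1e4,
    ## clock
    n_clock_probes = 50L,
    clock_adult_age = 20,
    delta_age_case1 = -1.51,
    delta_age_case2 = 9.73,
    clock_age_sd = 2,
    clock_beta_noise_sd = 0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("sim_config", "list"))
}

## derive a per-stage seed from the master seed, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647)
}

## alternating inter-LAD / LAD blocks along one chromosome; exponential
## block lengths (floored at 20% of the mean) sized so the expected LAD
## fraction equals cfg$lad_fraction
gen_lad_blocks <- function(chrom, len, frac, mean_lad) {
  if (frac >= 1) stop("LAD fraction must be < 1", call. = FALSE)
  if (mean_lad > len) stop("mean LAD length exceeds chromosome",
                           call. = FALSE)
  mean_inter <- mean_lad * (1 - frac) / frac
  draw <- function(m) max(0.2 * m, stats::rexp(1L, 1 / m))
  pos <- draw(mean_inter) / 2  # half-length first inter block
  lads <- list()
  while (pos < len) {
    w <- min(draw(mean_lad), len - pos)
    if (w >= 1) lads[[length(lads) + 1L]] <-
        data.frame(chrom = chrom, start = floor(pos), end = floor(pos + w))
    pos <- pos + w + draw(mean_inter)
  }
  if (length(lads) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  do.call(rbind, lads)
}

## sample n interval midpoints with probability p_lad of landing in `lads`
sample_positions <- function(n, lads, inter, p_lad) {
  pick_from <- function(track, k) {
    if (k == 0L || nrow(track) == 0L) {
      return(data.frame(chrom = character(), pos = numeric()))
    }
    w <- track$end - track$start
    idx <- sample.int(nrow(track), k, replace = TRUE, prob = w)
    off <- floor(stats::runif(k) * w[idx])
    data.frame(chrom = track$chrom[idx], pos = track$start[idx] + off)
  }
  k_lad <- if (nrow(lads) == 0L) 0L
           else if (nrow(inter) == 0L) n
           else stats::rbinom(1L, n, p_lad)
  out <- rbind(pick_from(lads, k_lad), pick_from(inter, n - k_lad))
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Generate a synthetic genome annotation
#'
#' Builds the interval scaffold every other generator consumes:
#' alternating LAD / inter-LAD blocks per autosome for lamin A and
#' (independently) lamin B, a PMD/HMD partition in which most lamin A LADs
#' are PMDs, histone-mark tracks with configured LAD affinity, gene bodies
#' placed mostly outside LADs, and a probe annotation with solo-WCGW /
#' PMD / HMD / sex-chromosome / SNP / cross-reactive flags. Probe density
#' inside LADs is reduced relative to outside (CpG-poor heterochromatin).
#' Deterministic given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `chrom_sizes`, tracks (`laminA`, `laminB`,
#'   `inter_laminA`, `pmd`, `hmd`, `histone` list), `genes` (data.frame),
#'   and `annot` (probe annotation data.frame).
#' @export
make_genome <- function(config = simulation_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 1L))
  autosomes <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                 autosomes)
  chrom_sizes["chrX"] <- cfg$sex_chrom_length

  blocks <- function() {
    do.call(rbind, lapply(autosomes, function(ch) {
      gen_lad_blocks(ch, cfg$chrom_length, cfg$lad_fraction,
                     cfg$lad_mean_length)
    }))
  }
  la <- blocks()
  lb <- blocks()
  laminA <- genomic_track(la$chrom, la$start, la$end,
                          track_name = "laminA_LAD")
  laminB <- genomic_track(lb$chrom, lb$start, lb$end,
                          track_name = "laminB_LAD")
  auto_sizes <- chrom_sizes[autosomes]
  inter_laminA <- track_complement(laminA, auto_sizes,
                                   track_name = "inter_laminA")

  ## PMD/HMD partition: lamin A LADs are PMDs with high probability
  pmd_rows <- rbind(
    la[stats::runif(nrow(la)) < cfg$pmd_given_lad, , drop = FALSE],
    local({
      il <- as.data.frame(inter_laminA)
      il[stats::runif(nrow(il)) < cfg$pmd_given_inter,
         c("chrom", "start", "end"), drop = FALSE]
    })
  )
  pmd <- if (nrow(pmd_rows) > 0L) {
    genomic_track(pmd_rows$chrom, pmd_rows$start, pmd_rows$end,
                  track_name = "PMD")
  } else genomic_track(character(), numeric(), numeric(), track_name = "PMD")
  hmd <- track_complement(pmd, auto_sizes, track_name = "HMD")

  ## histone-mark tracks with configured LAD affinity
  histone <- lapply(names(cfg$histone_marks), function(mk) {
    hm <- cfg$histone_marks[[mk]]
    ctr <- sample_positions(hm$n, as.data.frame(laminA),
                            as.data.frame(inter_laminA), hm$p_lad)
    w <- hm$width
    start <- pmax(0, ctr$pos - w / 2)
    genomic_track(ctr$chrom, start, start + w, track_name = mk)
  })
  names(histone) <- names(cfg$histone_marks)

  ## genes: bodies mostly in inter-LADs
  gctr <- sample_positions(cfg$n_genes, as.data.frame(laminA),
                           as.data.frame(inter_laminA), cfg$gene_p_lad)
  glen <- stats::runif(cfg$n_genes, cfg$gene_length_range[1],
                       cfg$gene_length_range[2])
  gstart <- pmax(0, floor(gctr$pos - glen / 2))
  gend <- pmin(cfg$chrom_length, floor(gctr$pos + glen / 2))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    chrom = gctr$chrom, start = gstart, end = gend,
    tss = ifelse(strand == "+", gstart, gend - 1),
    strand = strand, stringsAsFactors = FALSE
  )

  ## probes: autosomal placement with reduced density in LADs, plus chrX
  n_sex <- round(cfg$sex_probe_fraction * cfg$n_probes)
  n_auto <- cfg$n_probes - n_sex
  lad_bp <- sum(laminA$end - laminA$start)
  inter_bp <- sum(inter_laminA$end - inter_laminA$start)
  p_lad_probe <- cfg$lad_probe_density * lad_bp /
    (cfg$lad_probe_density * lad_bp + inter_bp)
  repeat {
    pos_auto <- sample_positions(n_auto, as.data.frame(laminA),
                                 as.data.frame(inter_laminA), p_lad_probe)
    pos_sex <- data.frame(
      chrom = "chrX",
      pos = sample.int(cfg$sex_chrom_length - 1L, n_sex)
    )
    ann <- rbind(pos_auto, pos_sex)
    ann$pos <- ann$pos + 1  # 1-based CpG coordinate
    if (!anyDuplicated(paste(ann$chrom, ann$pos))) break
  }
  ord <- order(ann$chrom, ann$pos)
  ann <- ann[ord, , drop = FALSE]
  annot <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(nrow(ann))),
    chrom = ann$chrom, pos = ann$pos, stringsAsFactors = FALSE
  )
  q <- probe_intervals(annot$chrom, annot$pos)
  annot$sex_chromosome <- annot$chrom == "chrX"
  annot$snp_affected <- stats::runif(nrow(annot)) < cfg$snp_fraction
  annot$cross_reactive <- stats::runif(nrow(annot)) <
    cfg$cross_reactive_fraction
  annot$island <- stats::runif(nrow(annot)) < cfg$island_fraction
  in_pmd <- overlaps_any(q, pmd) & !annot$sex_chromosome
  annot$in_pmd <- in_pmd & !annot$island
  annot$in_hmd <- !in_pmd & !annot$island & !annot$sex_chromosome
  annot$solo_wcgw <- stats::runif(nrow(annot)) < cfg$solo_wcgw_fraction
  annot$in_laminA <- overlaps_any(q, laminA)
  annot$in_laminB <- overlaps_any(q, laminB)

  list(chrom_sizes = chrom_sizes, laminA = laminA, laminB = laminB,
       inter_laminA = inter_laminA, pmd = pmd, hmd = hmd,
       histone = histone, genes = genes, annot = annot)
}

#' Generate a synthetic methylation experiment
#'
#' Draws a probes x samples beta matrix with the planted structure the
#' pipeline is designed to recover: a per-probe baseline mean by region
#' class (CpG island ~0.10, PMD ~0.60, HMD ~0.85), hypermethylation of
#' `lad_delta_beta` on the affected lamin A LAD probes in every case
#' sample, and an additional global shrinkage of means toward 0.5 (partial
#' methylation) in the `case2` subgroup. Values are Beta-distributed with
#' per-class concentrations; means are clipped to `config$clip` and an
#' error is raised if a planted effect would push a mean outside the valid
#' range by more than 0.05. Detection p-values are near 0 with a planted
#' fraction of failures. Deterministic given `seed`.
#'
#' @param genome output of [make_genome()].
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `beta`, `detection_p` (matrices), `sheet` (sample
#'   sheet data.frame), and `truth` (planted parameters: affected probe
#'   ids, per-probe true delta, subgroup labels).
#' @export
make_methylation <- function(genome, config = simulation_config(),
                             seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 2L))
  annot <- genome$annot
  n_probes <- nrow(annot)

  groups <- c(rep("control", cfg$n_control),
              rep("case", cfg$n_case1 + cfg$n_case2))
  subgroups <- c(rep("control", cfg$n_control),
                 rep("case1", cfg$n_case1), rep("case2", cfg$n_case2))
  n_samples <- length(groups)
  sheet <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    group = groups, subgroup = subgroups,
    age_years = ifelse(groups == "control",
                       round(stats::runif(n_samples, 25, 60), 1),
                       round(stats::runif(n_samples, 2, 14), 1)),
    passage = sample(8:16, n_samples, replace = TRUE),
    seeded = 1e5,
    stringsAsFactors = FALSE
  )
  sheet$harvested <- round(sheet$seeded *
                             2^stats::runif(n_samples, 1.5, 2.5))

  base_mean <- ifelse(annot$island, cfg$mean_island,
                      ifelse(annot$in_pmd, cfg$mean_pmd, cfg$mean_hmd))
  conc <- ifelse(annot$island, cfg$conc_island,
                 ifelse(annot$in_pmd, cfg$conc_pmd, cfg$conc_hmd))

  ## planted case hypermethylation on lamin A LAD probes
  eligible <- which(annot$in_laminA & !annot$sex_chromosome & !annot$island)
  n_aff <- if (!is.null(cfg$lad_effect_n)) min(cfg$lad_effect_n,
                                               length(eligible))
           else round(cfg$lad_effect_fraction * length(eligible))
  affected <- sort(sample(eligible, n_aff))
  true_delta <- numeric(n_probes)
  true_delta[affected] <- cfg$lad_delta_beta

  clip <- cfg$clip
  tol <- 0.05
  planted_max <- max(base_mean + true_delta)
  if (planted_max > clip[2] + tol || min(base_mean) < clip[1] - tol) {
    stop("planted effect pushes probe means outside the valid beta range",
         call. = FALSE)
  }

  beta <- matrix(NA_real_, n_probes, n_samples,
                 dimnames = list(annot$probe_id, sheet$sample_id))
  for (j in seq_len(n_samples)) {
    m <- base_mean
    if (groups[j] == "case") m <- m + true_delta
    if (subgroups[j] == "case2") {
      m <- m + cfg$pm_shift_strength * (0.5 - m)
    }
    m <- pmin(pmax(m, clip[1]), clip[2])
    beta[, j] <- stats::rbeta(n_probes, m * conc, (1 - m) * conc)
  }
  beta <- pmin(pmax(beta, 0), 1)

  detection_p <- matrix(stats::runif(n_probes * n_samples, 0, 0.005),
                        n_probes, n_samples,
                        dimnames = dimnames(beta))
  n_fail <- round(cfg$det_fail_fraction * n_probes)
  if (n_fail > 0L) {
    fail_probes <- sample.int(n_probes, n_fail)
    fail_samples <- sample.int(n_samples, n_fail, replace = TRUE)
    detection_p[cbind(fail_probes, fail_samples)] <-
      stats::runif(n_fail, 0.011, 0.2)
  }

  truth <- list(affected_probes = annot$probe_id[affected],
                true_delta = stats::setNames(true_delta, annot$probe_id),
                subgroup = stats::setNames(subgroups, sheet$sample_id),
                lad_delta_beta = cfg$lad_delta_beta,
                pm_shift_strength = cfg$pm_shift_strength)
  list(beta = beta, detection_p = detection_p, sheet = sheet, truth = truth)
}

#' Generate synthetic differential accessibility peaks
#'
#' Places a large background of non-differential candidate peaks uniformly
#' on the autosomes, plus gained and lost differential peaks whose
#' probability of falling inside a lamin A LAD is the LAD base-pair
#' fraction inflated by the configured enrichment factor (so the planted
#' signed fold enrichment relative to a uniform universe equals the
#' factor). q-values are consistent with the differential flag.
#' Deterministic given `seed`.
#'
#' @inheritParams make_methylation
#' @return list with `peaks` (data.frame `chrom`, `start`, `end`, `name`,
#'   `direction` in `{gained, lost, stable}`, `q_value`, `significant`)
#'   and `truth` (planted LAD membership and factors).
#' @export
make_diff_peaks <- function(genome, config = simulation_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 3L))
  lads <- as.data.frame(genome$laminA)
  inter <- as.data.frame(genome$inter_laminA)
  lad_bp <- sum(lads$end - lads$start)
  total_bp <- lad_bp + sum(inter$end - inter$start)
  lad_frac <- lad_bp / total_bp

  place <- function(n, p_lad) {
    ctr <- sample_positions(n, lads, inter, p_lad)
    w <- cfg$peak_width
    start <- pmax(0, floor(ctr$pos - w / 2))
    data.frame(chrom = ctr$chrom, start = start, end = start + w)
  }
  p_gained <- cfg$lad_peak_enrichment_gained * lad_frac
  p_lost <- cfg$lad_peak_enrichment_lost * lad_frac
  if (p_gained > 0.98 || p_lost > 0.98) {
    stop("LAD enrichment factor infeasible at this LAD fraction",
         call. = FALSE)
  }
  gained <- place(cfg$n_gained_peaks, p_gained)
  lost <- place(cfg$n_lost_peaks, p_lost)
  stable <- place(cfg$n_background_peaks, lad_frac)
  n_diff <- cfg$n_gained_peaks + cfg$n_lost_peaks
  peaks <- rbind(
    cbind(gained, direction = "gained"),
    cbind(lost, direction = "lost"),
    cbind(stable, direction = "stable")
  )
  peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$q_value <- c(stats::runif(n_diff, 1e-5, 0.049),
                     stats::runif(cfg$n_background_peaks, 0.06, 1))
  peaks$significant <- peaks$q_value < 0.05
  in_lad <- overlaps_any(peaks, genome$laminA)
  truth <- list(lad_fraction = lad_frac,
                factor_gained = cfg$lad_peak_enrichment_gained,
                factor_lost = cfg$lad_peak_enrichment_lost,
                in_laminA = stats::setNames(in_lad, peaks$name))
  list(peaks = peaks, truth = truth)
}

#' Generate a synthetic differential expression table and gene sets
#'
#' Selects the configured numbers of up- and downregulated genes, builds
#' accessibility- and methylation-linked gene sets with planted pairwise
#' and triple intersections, and places the expression-and-accessibility
#' coupled subset LAD-proximal (gene body within `lad_proximal_max` bp of
#' the lamin A / lamin B LAD union, preferring genes already there).
#' Expression is FPKM-scale log-normal with log2 fold changes around
#' +/- 1.5 for differential genes; q-values are consistent with the
#' significant flag. Deterministic given `seed`.
#'
#' @inheritParams make_methylation
#' @return list with `expression` (data.frame `gene_id`,
#'   `mean_fpkm_case`, `mean_fpkm_control`, `log2_fold_change`, `q_value`,
#'   `significant`), `gene_sets` (`de`, `accessible`, `methylated`), and
#'   `truth` (planted counts and the LAD distances of every gene).
#' @export
make_expression <- function(genome, config = simulation_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 4L))
  genes <- genome$genes
  lad_union <- track_union(genome$laminA, genome$laminB,
                           track_name = "LAD_union")
  dist <- nearest_distance(genes[, c("chrom", "start", "end")], lad_union)
  proximal_pool <- genes$gene_id[!is.na(dist) &
                                   dist <= cfg$lad_proximal_max]
  distal_pool <- setdiff(genes$gene_id, proximal_pool)

  n_de <- cfg$n_de_up + cfg$n_de_down
  ## the accessibility-coupled DE genes (incl. the triple overlap) are the
  ## LAD-proximal planted subset
  de_acc <- sample(proximal_pool, cfg$n_de_accessible)
  rest_pool <- setdiff(genes$gene_id, de_acc)
  de_rest <- sample(rest_pool, n_de - cfg$n_de_accessible)
  de <- c(de_acc, de_rest)
  triple <- sample(de_acc, cfg$n_triple)
  de_meth <- c(triple, sample(setdiff(de, de_acc),
                              cfg$n_de_methylated - cfg$n_triple))
  non_de <- setdiff(genes$gene_id, de)
  accessible <- c(de_acc, sample(non_de,
                                 cfg$n_accessible_genes -
                                   cfg$n_de_accessible))
  methylated <- c(de_meth,
                  sample(setdiff(non_de, accessible),
                         cfg$n_methylated_genes - cfg$n_de_methylated))

  is_de <- genes$gene_id %in% de
  direction <- integer(nrow(genes))
  de_idx <- which(is_de)
  up <- sample(de_idx, cfg$n_de_up)
  direction[up] <- 1L
  direction[setdiff(de_idx, up)] <- -1L

  base <- stats::rlnorm(nrow(genes), meanlog = 2, sdlog = 1)
  lfc <- ifelse(is_de,
                direction * stats::rnorm(nrow(genes), 1.5, 0.4),
                stats::rnorm(nrow(genes), 0, 0.1))
  expr <- data.frame(
    gene_id = genes$gene_id,
    mean_fpkm_control = base,
    mean_fpkm_case = base * 2^lfc,
    log2_fold_change = lfc,
    q_value = ifelse(is_de, stats::runif(nrow(genes), 1e-5, 0.049),
                     stats::runif(nrow(genes), 0.06, 1)),
    stringsAsFactors = FALSE
  )
  expr$significant <- expr$q_value < 0.05

  truth <- list(n_de = n_de, de_accessible = sort(de_acc),
                de_methylated = sort(de_meth), triple = sort(triple),
                lad_distance = stats::setNames(dist, genes$gene_id))
  list(expression = expr,
       gene_sets = list(de = sort(de), accessible = sort(accessible),
                        methylated = sort(methylated)),
       truth = truth)
}

#' Generate a synthetic epigenetic clock and matching beta columns
#'
#' Builds a sparse linear clock (random weights on dedicated clock
#' probes) and constructs, for every sample, clock-probe beta values that
#' invert the age transform exactly at the sample's planted DNAm age:
#' chronological age plus the configured subgroup offsets
#' (`delta_age_case1`, `delta_age_case2`) plus Gaussian jitter of
#' `clock_age_sd` years. With `clock_age_sd = 0` and
#' `clock_beta_noise_sd = 0` the round trip through [apply_clock()] is
#' exact. Deterministic given `seed`.
#'
#' @param sheet sample sheet from [make_methylation()].
#' @inheritParams make_methylation
#' @return list with `clock` (model list), `clock_beta` (clock probes x
#'   samples matrix) and `truth` (planted DNAm ages and offsets).
#' @export
make_clock <- function(sheet, config = simulation_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 5L))
  np <- cfg$n_clock_probes
  ids <- sprintf("clk%03d", seq_len(np))
  w <- sample(c(-1, 1), np, replace = TRUE) * stats::runif(np, 0.3, 0.6)
  beta0 <- stats::runif(np, 0.3, 0.7)
  intercept <- -sum(w * beta0)  # baseline score 0 -> age = adult_age
  clock <- list(intercept = intercept,
                weights = stats::setNames(w, ids),
                adult_age = cfg$clock_adult_age)

  offset <- c(control = 0, case1 = cfg$delta_age_case1,
              case2 = cfg$delta_age_case2)[sheet$subgroup]
  target_age <- pmax(0.5, sheet$age_years + offset +
                       stats::rnorm(nrow(sheet), 0, cfg$clock_age_sd))
  target_score <- clock_transform_inverse(target_age, cfg$clock_adult_age)
  sw2 <- sum(w^2)
  clock_beta <- vapply(target_score, function(s) beta0 + s * w / sw2,
                       numeric(np))
  if (cfg$clock_beta_noise_sd > 0) {
    clock_beta <- clock_beta +
      stats::rnorm(length(clock_beta), 0, cfg$clock_beta_noise_sd)
  }
  clock_beta <- pmin(pmax(clock_beta, 0), 1)
  dimnames(clock_beta) <- list(ids, sheet$sample_id)
  truth <- list(dnam_age = stats::setNames(target_age, sheet$sample_id),
                offset = stats::setNames(offset, sheet$sample_id))
  list(clock = clock, clock_beta = clock_beta, truth = truth)
}

#' Simulate a complete study directory
#'
#' Runs every generator with sub-seeds derived from one master seed and
#' writes a self-contained input directory: BED tracks (lamin A / lamin B
#' LADs, inter-LADs, PMD/HMD, histone marks), the probe annotation, beta
#' and detection-p matrices, sample sheet, differential peak and
#' expression tables, gene sets, clock files, the planted-truth record and
#' a copy of the configuration. Rerunning with the same configuration and
#' seed reproduces every file byte for byte.
#'
#' @param dir output directory (created if needed).
#' @param config a [simulation_config()].
#' @param seed master integer seed.
#' @return (invisibly) a list with the in-memory objects: `genome`,
#'   `meth`, `peaks`, `expr`, `clockset`, and `dir`.
#' @export
simulate_study <- function(dir, config = simulation_config(), seed = 1) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  genome <- make_genome(config, seed)
  meth <- make_methylation(genome, config, seed)
  peaks <- make_diff_peaks(genome, config, seed)
  expr <- make_expression(genome, config, seed)
  clockset <- make_clock(meth$sheet, config, seed)

  tr <- file.path(dir, "tracks")
  write_bed(genome$laminA, file.path(tr, "laminA_LAD.bed"))
  write_bed(genome$laminB, file.path(tr, "laminB_LAD.bed"))
  write_bed(genome$inter_laminA, file.path(tr, "inter_laminA.bed"))
  write_bed(genome$pmd, file.path(tr, "PMD.bed"))
  write_bed(genome$hmd, file.path(tr, "HMD.bed"))
  for (mk in names(genome$histone)) {
    write_bed(genome$histone[[mk]], file.path(tr, paste0(mk, ".bed")))
  }
  write_tsv_table(data.frame(chrom = names(genome$chrom_sizes),
                             length = unname(genome$chrom_sizes)),
                  file.path(dir, "chrom_sizes.tsv"))
  write_tsv_table(genome$genes, file.path(dir, "genes.tsv"))
  write_tsv_table(genome$annot, file.path(dir, "probe_annotation.tsv"))
  write_beta_matrix(meth$beta, file.path(dir, "beta.tsv"))
  write_beta_matrix(meth$detection_p, file.path(dir, "detection_p.tsv"))
  write_tsv_table(meth$sheet, file.path(dir, "sample_sheet.tsv"))
  write_tsv_table(peaks$peaks[, c("chrom", "start", "end", "name",
                                  "direction", "q_value", "significant")],
                  file.path(dir, "diff_peaks.tsv"))
  write_tsv_table(expr$expression, file.path(dir, "expression.tsv"))
  writeLines(expr$gene_sets$accessible,
             file.path(dir, "accessible_genes.txt"))
  writeLines(expr$gene_sets$methylated,
             file.path(dir, "methylated_genes.txt"))
  write_clock(clockset$clock, file.path(dir, "clock_weights.tsv"),
              file.path(dir, "clock_config.json"))
  write_beta_matrix(clockset$clock_beta, file.path(dir, "clock_beta.tsv"))

  truth <- list(
    methylation = lapply(meth$truth, unclass),
    peaks = lapply(peaks$truth, unclass),
    expression = lapply(expr$truth, unclass),
    clock = lapply(clockset$truth, unclass),
    seed = seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = genome, meth = meth, peaks = peaks, expr = expr,
                 clockset = clockset, dir = dir))
}
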