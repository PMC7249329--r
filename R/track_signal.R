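#' Call poised enhancers from H3K4me1 peak pairs
#'
#' Poised enhancers are defined as regions containing pairs of H3K4me1
#' peaks in close proximity: adjacent same-chromosome peaks whose
#' edge-to-edge gap (start of next minus end of previous) is strictly less
#' than `max_pair_gap` are chained, and each maximal chain of two or more
#' peaks emits one region spanning from the first peak's start to the last
#' peak's end. With `gap_mode = "center"` the gap is measured between peak
#' midpoints instead; with `chain = FALSE` only consecutive pairs are
#' emitted (one region per qualifying pair).
#'
#' @param peaks a [genomic_track()] of H3K4me1 peaks.
#' @param max_pair_gap gap threshold in bp (default 1500, exclusive).
#' @param gap_mode `"edge"` (default) or `"center"`.
#' @param chain merge runs of nearby peaks into maximal regions (default
#'   `TRUE`).
#' @return A [genomic_track()] of non-overlapping enhancer regions, each
#'   containing >= 2 input peaks; `score` holds the number of member
#'   peaks.
#' @export
call_poised_enhancers <- function(peaks, max_pair_gap = 1500,
                                  gap_mode = c("edge", "center"),
                                  chain = TRUE) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(peaks) == 0L) {
    return(genomic_track(character(), numeric(), numeric(),
                         track_name = "poised_enhancers"))
  }
  df <- as.data.frame(peaks)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  regions <- list()
  for (ch in unique(df$chrom)) {
    p <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(p)
    if (n < 2L) next
    gap <- if (gap_mode == "edge") {
      p$start[-1L] - cummax(p$end)[-n]
    } else {
      mid <- (p$start + p$end) / 2
      mid[-1L] - mid[-n]
    }
    near <- gap < max_pair_gap
    if (chain) {
      run_id <- cumsum(c(0L, !near))
      for (g in split(seq_len(n), run_id)) {
        if (length(g) >= 2L) {
          regions[[length(regions) + 1L]] <-
            data.frame(chrom = ch, start = p$start[g[1L]],
                       end = max(p$end[g]), n_peaks = length(g))
        }
      }
    } else {
      for (i in which(near)) {
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = ch, start = p$start[i],
                     end = max(p$end[i:(i + 1L)]), n_peaks = 2L)
      }
    }
  }
  if (length(regions) == 0L) {
    return(genomic_track(character(), numeric(), numeric(),
                         track_name = "poised_enhancers"))
  }
  out <- do.call(rbind, regions)
  genomic_track(out$chrom, out$start, out$end, score = out$n_peaks,
                track_name = "poised_enhancers")
}

#' ChIP over input log2 enrichment across LAD and inter-LAD segments
#'
#' Per region, computes `log2((chip + eps) / (input + eps))` from mean
#' ChIP and input signal, classifies each region as LAD or inter-LAD by
#' overlap with the supplied tracks, and compares the two log-ratio
#' distributions by a two-sided Wilcoxon rank-sum test.
#'
#' @param chip,input data.frames with `chrom`, `start`, `end`, `value`
#'   (mean signal per region, >= 0), keyed to identical region sets in
#'   identical order.
#' @param lads,inter_lads [genomic_track()] objects defining the two
#'   region classes.
#' @param pseudocount epsilon added to both numerator and denominator
#'   (default 0.5) so zero-coverage regions stay finite.
#' @return list with `regions` (the input regions plus `class` and
#'   `log2_ratio`), `median_lad`, `median_inter_lad`, `W`, `p`.
#' @export
lad_signal_enrichment <- function(chip, input, lads, inter_lads,
                                  pseudocount = 0.5) {
  key_c <- paste(chip$chrom, chip$start, chip$end)
  key_i <- paste(input$chrom, input$start, input$end)
  if (!identical(key_c, key_i)) {
    stop("chip and input are keyed to different region sets", call. = FALSE)
  }
  if (any(chip$value < 0) || any(input$value < 0)) {
    stop("signal values must be non-negative", call. = FALSE)
  }
  ratio <- log2((chip$value + pseudocount) / (input$value + pseudocount))
  in_lad <- overlaps_any(chip, lads)
  in_inter <- overlaps_any(chip, inter_lads)
  cls <- ifelse(in_lad, "LAD", ifelse(in_inter, "inter_LAD", NA))
  regions <- data.frame(chip[, c("chrom", "start", "end")],
                        chip = chip$value, input = input$value,
                        log2_ratio = ratio, class = cls,
                        stringsAsFactors = FALSE)
  x <- ratio[cls == "LAD" & !is.na(cls)]
  y <- ratio[cls == "inter_LAD" & !is.na(cls)]
  wt <- wilcoxon_rank_sum(x, y)
  list(regions = regions,
       median_lad = stats::median(x),
       median_inter_lad = stats::median(y),
       W = wt$W, p = wt$p)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. The p-value uses exact
#' enumeration when `length(x) + length(y) <= 12` and there are no ties,
#' and otherwise the normal approximation with tie-corrected variance and
#' a 0.5 continuity correction (via [stats::wilcox.test()]). Two samples
#' forming a single constant multiset give `p = 1`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return list with `W` (rank-sum statistic, number of (x, y) pairs with
#'   x > y counting ties as 1/2) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  r <- rank(c(x, y))
  w <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) return(list(W = w, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = continuity)
  )
  list(W = unname(wt$statistic), p = wt$p.value)
}
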