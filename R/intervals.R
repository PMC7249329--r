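#' Genomic interval tracks
#'
#' A `genomic_track` is a named set of genomic intervals in 0-based,
#' half-open (BED) coordinates: an interval covers bases `[start, end)`.
#' It is stored as a plain `data.frame` with columns `chrom`, `start`,
#' `end`, `name`, `score`, `strand`, kept sorted by `(chrom, start, end)`.
#' Overlapping intervals are allowed and never merged implicitly.
#'
#' All overlap and distance queries in the package are strand-agnostic.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `start >= 0`, `end > start`.
#' @param name optional interval labels.
#' @param score optional numeric scores.
#' @param strand optional strand (`"+"`, `"-"` or `"."`).
#' @param track_name label for the track (e.g. `"laminA_LAD"`).
#'
#' @return A `genomic_track` object (a sorted `data.frame` with attribute
#'   `track_name`).
#' @export
genomic_track <- function(chrom, start, end, name = NA_character_,
                          score = NA_real_, strand = ".",
                          track_name = "track") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, track_name = track_name,
            class = c("genomic_track", "data.frame"))
}

validate_intervals <- function(df, lines = NULL) {
  bad_chrom <- !nzchar(df$chrom) | is.na(df$chrom)
  bad_coord <- is.na(df$start) | is.na(df$end) | df$start < 0 |
    df$end <= df$start
  if (any(bad_chrom) || any(bad_coord)) {
    idx <- which(bad_chrom | bad_coord)[1L]
    where <- if (!is.null(lines)) sprintf(" (line %d)", lines[idx]) else
      sprintf(" (row %d)", idx)
    stop("invalid interval", where,
         ": chrom must be non-empty, start >= 0 and end > start ",
         "(0-based half-open)", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.genomic_track <- function(x, ...) {
  cat(sprintf("genomic_track '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "track_name"), nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Normalize chromosome naming between "1" and "chr1" dialects
#'
#' Public annotation tracks mix UCSC-style ("chr1") and Ensembl-style ("1")
#' names. This maps every name to the UCSC dialect ("chr"-prefixed).
#'
#' @param chrom character vector of chromosome names.
#' @return character vector with a `chr` prefix on every name.
#' @export
normalize_chrom <- function(chrom) {
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

## Internal: genomic_track (or compatible data.frame) -> GRanges.
## BED [start, end) becomes 1-based closed [start+1, end], so half-open
## semantics (abutting => no overlap, distance 0) are preserved exactly.
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Read a BED file into a genomic track
#'
#' Accepts BED3+ (tab-separated, at least `chrom start end`); `track` and
#' `browser` header lines and `#` comments are skipped. Coordinates are kept
#' verbatim in the BED 0-based half-open convention.
#'
#' @param path path to a BED file.
#' @param track_name label for the returned track; defaults to the file name.
#' @param normalize_chroms if `TRUE`, map chromosome names to the "chr"
#'   dialect via [normalize_chrom()].
#' @return A [genomic_track()].
#' @export
read_bed <- function(path, track_name = NULL, normalize_chroms = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser)\\b|^#|^\\s*$", raw)
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(genomic_track(character(), numeric(), numeric(),
                         track_name = track_name %||% basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("BED parse error at line ", line_no[which(ncols < 3L)[1L]],
         ": fewer than 3 tab-separated columns", call. = FALSE)
  }
  grab <- function(i, default) {
    default <- as.character(default)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.numeric(grab(2L, NA)))
  end <- suppressWarnings(as.numeric(grab(3L, NA)))
  nonint <- is.na(start) | is.na(end) | start != floor(start) |
    end != floor(end)
  if (any(nonint)) {
    stop("BED parse error at line ", line_no[which(nonint)[1L]],
         ": non-integer coordinates", call. = FALSE)
  }
  chrom <- grab(1L, NA)
  if (normalize_chroms) chrom <- normalize_chrom(chrom)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = grab(4L, NA_character_),
                   score = suppressWarnings(as.numeric(grab(5L, NA))),
                   strand = grab(6L, "."),
                   stringsAsFactors = FALSE)
  tryCatch(validate_intervals(df, lines = line_no), error = function(e) {
    stop("BED parse error: ", conditionMessage(e), call. = FALSE)
  })
  genomic_track(df$chrom, df$start, df$end, df$name, df$score, df$strand,
                track_name = track_name %||% basename(path))
}

#' Write a genomic track as BED
#'
#' Emits 3 or 6 columns; missing `name`/`score`/`strand` entries fall back
#' to `"."`, `0` and `"."` when a 6-column file is requested.
#'
#' @param track a [genomic_track()].
#' @param path output file path.
#' @param columns number of BED columns to write (3 or 6).
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path, columns = 6L) {
  stopifnot(columns %in% c(3L, 6L))
  df <- as.data.frame(track)
  out <- data.frame(df$chrom, format_bed_coord(df$start),
                    format_bed_coord(df$end))
  if (columns == 6L) {
    out$name <- ifelse(is.na(df$name), ".", df$name)
    out$score <- ifelse(is.na(df$score), 0, df$score)
    out$strand <- ifelse(is.na(df$strand), ".", df$strand)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bed_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag query intervals that overlap a track
#'
#' A query overlaps iff it shares at least one base with some track interval
#' on the same chromosome. Under half-open coordinates, `[0,100)` and
#' `[100,200)` do not overlap.
#'
#' @param queries a [genomic_track()] or data.frame with `chrom`, `start`,
#'   `end`.
#' @param track a [genomic_track()].
#' @return logical vector, one flag per query (all `FALSE` for an empty
#'   track).
#' @export
overlaps_any <- function(queries, track) {
  if (nrow(queries) == 0L) return(logical(0))
  if (nrow(track) == 0L) return(rep(FALSE, nrow(queries)))
  ## seqlevel mismatch between query and track is a legitimate "no
  ## overlap", not a condition worth surfacing
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(queries), as_granges(track))
  )
  out <- rep(FALSE, nrow(queries))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Distance from each query to the nearest track interval
#'
#' Returns 0 for overlapping queries; otherwise the gap in bases between the
#' query and the closest same-chromosome track interval (abutting intervals
#' have distance 0). Queries on chromosomes absent from the track get `NA`
#' ("undefined"); callers exclude these from medians.
#'
#' @inheritParams overlaps_any
#' @return numeric vector of non-negative distances (bp), `NA` where
#'   undefined.
#' @export
nearest_distance <- function(queries, track) {
  if (nrow(track) == 0L) stop("nearest_distance: empty track", call. = FALSE)
  if (nrow(queries) == 0L) return(numeric(0))
  q <- as_granges(queries)
  s <- as_granges(track)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE)
  )
  out <- rep(NA_real_, nrow(queries))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Merge overlapping or abutting intervals of a track
#'
#' Used to build union tracks (e.g. lamin A and/or lamin B LADs).
#'
#' @param ... one or more [genomic_track()] objects.
#' @param track_name name for the merged track.
#' @return A [genomic_track()] with disjoint, sorted intervals.
#' @export
track_union <- function(..., track_name = "union") {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  if (nrow(df) == 0L) {
    return(genomic_track(character(), numeric(), numeric(),
                         track_name = track_name))
  }
  red <- GenomicRanges::reduce(as_granges(df))
  genomic_track(as.character(GenomicRanges::seqnames(red)),
                GenomicRanges::start(red) - 1L,
                GenomicRanges::end(red),
                track_name = track_name)
}

#' Complement of a track within chromosome bounds
#'
#' Returns the segments not covered by `track` on each chromosome, e.g.
#' inter-LADs between LADs.
#'
#' @param track a [genomic_track()].
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param track_name name for the complement track.
#' @return A [genomic_track()].
#' @export
track_complement <- function(track, chrom_sizes, track_name = "complement") {
  out <- list()
  for (ch in names(chrom_sizes)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    len <- chrom_sizes[[ch]]
    if (nrow(sub) == 0L) {
      out[[ch]] <- data.frame(chrom = ch, start = 0, end = len)
      next
    }
    red <- GenomicRanges::reduce(as_granges(sub))
    s <- GenomicRanges::start(red) - 1L
    e <- GenomicRanges::end(red)
    gaps_start <- c(0, e)
    gaps_end <- c(s, len)
    keep <- gaps_end > gaps_start
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = gaps_start[keep],
                              end = gaps_end[keep])
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric())
  genomic_track(df$chrom, df$start, df$end, track_name = track_name)
}

#' Convert 1-based probe positions to point intervals
#'
#' Array manifests give 1-based CpG coordinates; internally everything is
#' 0-based half-open, so position `pos` becomes `[pos-1, pos)`.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions.
#' @param name labels (e.g. probe ids).
#' @return A data.frame usable as the `queries` argument of
#'   [overlaps_any()] / [nearest_distance()].
#' @export
probe_intervals <- function(chrom, pos, name = NULL) {
  stopifnot(all(pos >= 1))
  data.frame(chrom = as.character(chrom), start = pos - 1, end = pos,
             name = name %||% NA_character_, stringsAsFactors = FALSE)
}
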