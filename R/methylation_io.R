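#' Per-CpG methylation tracks
#'
#' A methylation track is a plain tibble with one row per cytosine record:
#' columns `chrom`, `pos` (1-based position of the cytosine), `strand`
#' (`"+"`/`"-"`), `context` (usually `"CG"`), `meth_count`, `total_count`
#' and `ratio` (= `meth_count / total_count`, `NA` when uncovered).
#' Tracks are kept sorted by `(chrom, pos, strand)` with no duplicate keys.
#'
#' Genomic interval sets (LMR/UMR segments, annotations) are tibbles with
#' `chrom`, `start` (0-based inclusive), `end` (0-based exclusive) and
#' optionally `segment_class`, `n_cpgs`, `mean_methylation` — the BED
#' convention, so BED files round-trip coordinate-exactly.
#'
#' @name methylation-track
NULL

new_track <- function(chrom, pos, strand, context, meth_count, total_count) {
  tibble::tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    strand = as.character(strand),
    context = as.character(context),
    meth_count = as.integer(meth_count),
    total_count = as.integer(total_count),
    ratio = ifelse(total_count > 0, meth_count / total_count, NA_real_)
  )
}

empty_track <- function() {
  new_track(character(), integer(), character(), character(), integer(), integer())
}

validate_track <- function(track, what = "track") {
  bad <- which(track$meth_count > track$total_count)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: meth_count > total_count at %d record(s), first at row %d (%s:%d)",
      what, length(bad), bad[1], track$chrom[bad[1]], track$pos[bad[1]]
    ))
  }
  if (any(track$pos < 1L)) abort(sprintf("%s: positions must be >= 1", what))
  if (any(track$meth_count < 0L | track$total_count < 0L)) {
    abort(sprintf("%s: negative read counts", what))
  }
  invisible(track)
}

sort_track <- function(track) {
  track <- dplyr::arrange(track, .data$chrom, .data$pos, .data$strand)
  dplyr::distinct(track, .data$chrom, .data$pos, .data$strand, .keep_all = TRUE)
}

#' Read a per-CpG methylation call table
#'
#' Reads methratio-style TSV output (columns `chrom`, `pos`, `strand`,
#' `context`, `ratio`, `meth_count`, `total_count`; header optional; extra
#' columns ignored) or a bedGraph of methylation ratios paired with a
#' coverage bedGraph. Ratios are always recomputed from the counts, never
#' trusted from the file.
#'
#' @param path Path to the methylation table (TSV) or ratio bedGraph.
#' @param dialect `"methratio"` (default) or `"bedgraph"`.
#' @param coverage_path For `dialect = "bedgraph"`, path to the matching
#'   coverage bedGraph (same intervals, value = total read count).
#' @return A sorted, deduplicated methylation track tibble
#'   (see [methylation-track]).
#' @export
read_methratio <- function(path, dialect = c("methratio", "bedgraph"),
                           coverage_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "methratio") {
    track <- parse_methratio_tsv(path)
  } else {
    if (is.null(coverage_path)) {
      abort("dialect = \"bedgraph\" needs a matching `coverage_path`")
    }
    track <- parse_bedgraph_pair(path, coverage_path)
  }
  validate_track(track, what = basename(path))
  sort_track(track)
}

parse_methratio_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_track())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # header detection: second column must be an integer position
  has_header <- is.na(suppressWarnings(as.integer(fields[[1]][2])))
  offset <- if (has_header) 1L else 0L
  if (has_header) fields <- fields[-1]
  if (length(fields) == 0) return(empty_track())
  nf <- lengths(fields)
  bad <- which(nf < 7L)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (expected >= 7 tab-separated fields, got %d)",
                  basename(path), bad[1] + offset, nf[bad[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:7))
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 6]))
  tot <- suppressWarnings(as.integer(m[, 7]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(tot))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (non-numeric position or counts)",
                  basename(path), bad[1] + offset))
  }
  new_track(m[, 1], pos, m[, 3], m[, 4], meth, tot)
}

parse_bedgraph_pair <- function(ratio_path, coverage_path) {
  cols <- readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), value = readr::col_double()
  )
  rd <- function(p) readr::read_tsv(p, col_names = c("chrom", "start", "end", "value"),
                                    col_types = cols, comment = "#", progress = FALSE)
  ratios <- rd(ratio_path)
  covs <- rd(coverage_path)
  joined <- dplyr::inner_join(ratios, covs, by = c("chrom", "start", "end"),
                              suffix = c("_ratio", "_cov"))
  if (nrow(joined) != nrow(ratios)) {
    abort(sprintf("%s: %d interval(s) missing from coverage bedGraph",
                  basename(ratio_path), nrow(ratios) - nrow(joined)))
  }
  tot <- as.integer(round(joined$value_cov))
  new_track(joined$chrom, joined$start + 1L, "+", "CG",
            as.integer(round(joined$value_ratio * tot)), tot)
}

#' Write a methylation track as a methratio-style TSV
#'
#' @param track A methylation track tibble.
#' @param path Output path.
#' @param header Write a header line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_methratio <- function(track, path, header = TRUE) {
  out <- dplyr::select(track, "chrom", "pos", "strand", "context",
                       "ratio", "meth_count", "total_count")
  out$ratio <- ifelse(is.na(out$ratio), 0, out$ratio)
  readr::write_tsv(out, path, col_names = header, progress = FALSE)
  invisible(path)
}

#' Filter CpG records by read coverage
#'
#' Retains records with `total_count >= min_total` (or `> min_total` when
#' `strict = TRUE`). The genome-wide analysis default follows the rule that
#' only CpGs covered by at least three reads are considered.
#'
#' @param track A methylation track tibble.
#' @param min_total Minimum total read count (default 3).
#' @param strict Use a strict inequality (`>`)? Default `FALSE` (`>=`).
#' @return The filtered track, order preserved.
#' @export
filter_by_coverage <- function(track, min_total = 3, strict = FALSE) {
  stopifnot(min_total >= 0)
  keep <- if (strict) track$total_count > min_total else track$total_count >= min_total
  track[keep, , drop = FALSE]
}

#' Merge plus/minus strand records of each CpG dyad
#'
#' Records on the minus strand (position = plus position + 1) are merged
#' into their dyad anchor by summing read counts; all output records carry
#' strand `"+"`. Total methylated and total read counts are conserved.
#'
#' @param track A methylation track tibble.
#' @return A strand-combined track.
#' @export
aggregate_strands <- function(track) {
  if (nrow(track) == 0) return(track)
  anchor <- ifelse(track$strand == "-", track$pos - 1L, track$pos)
  agg <- track %>%
    dplyr::mutate(pos = anchor) %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::summarise(
      context = dplyr::first(.data$context),
      meth_count = sum(.data$meth_count),
      total_count = sum(.data$total_count),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      strand = "+",
      ratio = ifelse(.data$total_count > 0, .data$meth_count / .data$total_count, NA_real_)
    ) %>%
    dplyr::select("chrom", "pos", "strand", "context",
                  "meth_count", "total_count", "ratio")
  sort_track(agg)
}

#' Mean methylation in sliding windows
#'
#' Averages per-CpG methylation ratios in fixed-width windows along each
#' chromosome (the genome-wide methylation-landscape summary; violin plots
#' of these values characterize a methylome). The default is a
#' non-overlapping 2-kb tiling; set `step_bp < window_bp` for overlapping
#' windows. Windows containing no covered CpG are omitted.
#'
#' @param track A methylation track tibble.
#' @param window_bp Window width in bp (default 2000).
#' @param step_bp Step between window starts in bp (default `window_bp`).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open),
#'   `n_cpgs`, `mean_methylation`.
#' @export
sliding_window_methylation <- function(track, window_bp = 2000, step_bp = window_bp) {
  stopifnot(window_bp > 0, step_bp > 0)
  track <- track[!is.na(track$ratio), , drop = FALSE]
  if (nrow(track) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          n_cpgs = integer(), mean_methylation = double()))
  }
  purrr::map_dfr(split(track, track$chrom), function(tr) {
    max_pos <- max(tr$pos)
    starts <- seq(0L, max(0L, max_pos - 1L), by = step_bp)
    # window [s, s + window_bp) in 0-based coords covers 1-based pos s+1 .. s+window_bp
    win <- IRanges::IRanges(start = starts + 1L, width = window_bp)
    cpg <- IRanges::IRanges(start = tr$pos, width = 1L)
    hits <- IRanges::findOverlaps(cpg, win)
    if (length(hits) == 0) return(NULL)
    tibble::tibble(
      win = S4Vectors::subjectHits(hits),
      ratio = tr$ratio[S4Vectors::queryHits(hits)]
    ) %>%
      dplyr::group_by(.data$win) %>%
      dplyr::summarise(n_cpgs = dplyr::n(),
                       mean_methylation = mean(.data$ratio), .groups = "drop") %>%
      dplyr::transmute(
        chrom = tr$chrom[1],
        start = starts[.data$win],
        end = starts[.data$win] + as.integer(window_bp),
        n_cpgs = .data$n_cpgs,
        mean_methylation = .data$mean_methylation
      )
  }) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Mean methylation of a track over a set of intervals
#'
#' For each interval, the unweighted mean of per-CpG methylation ratios over
#' the CpGs that pass the coverage rule (`total_count >= min_total`, or `>`
#' when `strict`). Intervals with no qualifying CpG get `NA`. For the LMR
#' clock the rule is per-strand coverage strictly greater than 5, applied to
#' strand-resolved records.
#'
#' @param track A methylation track tibble.
#' @param intervals An interval tibble (`chrom`, `start`, `end`; BED
#'   0-based half-open).
#' @param min_total Coverage threshold (default 0 = no filter).
#' @param strict Strict inequality? Default `FALSE`.
#' @return `intervals` with `mean_methylation` and `n_cpgs` (number of
#'   qualifying CpGs) columns replaced/added, row order preserved.
#' @export
interval_methylation <- function(track, intervals, min_total = 0, strict = FALSE) {
  track <- filter_by_coverage(track, min_total, strict)
  track <- track[!is.na(track$ratio), , drop = FALSE]
  out <- intervals
  out$mean_methylation <- NA_real_
  out$n_cpgs <- 0L
  if (nrow(track) == 0 || nrow(intervals) == 0) return(out)
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0) next
    # 1-based CpG pos p lies in [start, end) iff start < p <= end
    ir <- IRanges::IRanges(start = intervals$start[ii] + 1L, end = intervals$end[ii])
    cpg <- IRanges::IRanges(start = track$pos[ti], width = 1L)
    hits <- IRanges::findOverlaps(cpg, ir)
    if (length(hits) == 0) next
    sums <- tibble::tibble(
      iv = S4Vectors::subjectHits(hits),
      ratio = track$ratio[ti[S4Vectors::queryHits(hits)]]
    ) %>%
      dplyr::group_by(.data$iv) %>%
      dplyr::summarise(m = mean(.data$ratio), n = dplyr::n(), .groups = "drop")
    out$mean_methylation[ii[sums$iv]] <- sums$m
    out$n_cpgs[ii[sums$iv]] <- sums$n
  }
  out
}

#' Read/write genomic interval sets as BED
#'
#' BED3/BED6 with 0-based half-open coordinates. On write, the BED name
#' field carries `segment_class` and the score field `n_cpgs`; on read they
#' are restored when present. Round trips are coordinate-exact.
#'
#' @param path BED file path.
#' @return `read_intervals_bed()`: an interval tibble sorted by
#'   `(chrom, start)`.
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          segment_class = character(), n_cpgs = integer(),
                          mean_methylation = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3) abort(sprintf("%s: BED needs >= 3 columns", basename(path)))
  m <- do.call(rbind, lapply(fields, function(f) f[1:min(length(f), 6)]))
  out <- tibble::tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    segment_class = if (ncol(m) >= 4) as.character(m[, 4]) else "generic",
    n_cpgs = if (ncol(m) >= 5) suppressWarnings(as.integer(m[, 5])) else NA_integer_,
    mean_methylation = NA_real_
  )
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at line %d", basename(path), bad[1]))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' @rdname read_intervals_bed
#' @param intervals An interval tibble.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (any(intervals$start >= intervals$end)) abort("intervals with start >= end")
  cls <- if ("segment_class" %in% names(intervals)) intervals$segment_class else "generic"
  score <- if ("n_cpgs" %in% names(intervals)) intervals$n_cpgs else 0L
  out <- tibble::tibble(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = ifelse(is.na(cls), "generic", cls),
    score = ifelse(is.na(score), 0L, score),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `file_path`, `tissue`, `age_days`, `group`.
#'
#' @param path CSV path.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "tissue", "age_days")
  missing <- setdiff(needed, names(sheet))
  if (length(missing) > 0) {
    abort(sprintf("sample sheet %s lacks column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample_id in sample sheet")
  sheet
}
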