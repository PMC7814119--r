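#' Segmentation configuration
#'
#' Parameters for low-methylated-region (LMR) calling. The segmentation is a
#' running-mean smoothing of per-CpG methylation ratios followed by
#' cutoff-run detection: maximal runs of consecutive CpGs whose smoothed
#' ratio falls strictly below `m_cutoff` become segments, short runs are
#' dropped, and segments are classed UMR (long, CpG-rich, typically
#' promoter CpG islands) or LMR (short, typically distal regulatory
#' elements) by CpG count.
#'
#' @param smooth_k Odd number of CpGs in the running-mean window (default 3).
#' @param m_cutoff Methylation cutoff in (0, 1) (default 0.5); can be
#'   replaced by an FDR-calibrated value via [calibrate_cutoff_fdr()].
#' @param min_cpgs_segment Minimum CpGs per reported segment (default 4).
#' @param umr_cpg_threshold Segments with at least this many CpGs are
#'   classed UMR rather than LMR (default 30).
#' @param fdr_target Target false-discovery proportion for cutoff
#'   calibration (default 0.05).
#' @param null_shuffles Number of shuffled-methylome replicates used to
#'   estimate the null segment count (default 10).
#' @param seed Seed for the shuffle null.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(smooth_k = 3, m_cutoff = 0.5,
                                min_cpgs_segment = 4, umr_cpg_threshold = 30,
                                fdr_target = 0.05, null_shuffles = 10,
                                seed = 1L) {
  stopifnot(smooth_k >= 1, smooth_k %% 2 == 1,
            m_cutoff > 0, m_cutoff < 1,
            min_cpgs_segment >= 1,
            fdr_target > 0, fdr_target < 1,
            null_shuffles >= 1)
  structure(list(smooth_k = as.integer(smooth_k), m_cutoff = m_cutoff,
                 min_cpgs_segment = as.integer(min_cpgs_segment),
                 umr_cpg_threshold = as.integer(umr_cpg_threshold),
                 fdr_target = fdr_target,
                 null_shuffles = as.integer(null_shuffles),
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

# running mean of x over k nearest positions, window truncated at the edges
running_mean_truncated <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n <= 1) return(x)
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth per-CpG methylation ratios
#'
#' Adds a `smoothed` column: the mean ratio over the `smooth_k` nearest
#' CpGs on the same chromosome centered at each CpG (truncated at
#' chromosome edges). Records with undefined ratios are dropped first.
#'
#' @param track A coverage-filtered methylation track tibble.
#' @param smooth_k Odd window size in CpGs (default 3).
#' @return The track with a `smoothed` column, sorted by `(chrom, pos)`.
#' @export
smooth_methylation <- function(track, smooth_k = 3) {
  stopifnot(smooth_k >= 1, smooth_k %% 2 == 1)
  track <- track[!is.na(track$ratio), , drop = FALSE]
  track <- dplyr::arrange(track, .data$chrom, .data$pos)
  track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(smoothed = running_mean_truncated(.data$ratio, .env$smooth_k)) %>%
    dplyr::ungroup()
}

# segment counts per cutoff from a smoothed track; cheap helper shared by
# segmentation and FDR calibration
count_segments <- function(smoothed_by_chrom, cutoffs, min_cpgs) {
  counts <- numeric(length(cutoffs))
  for (vals in smoothed_by_chrom) {
    for (k in seq_along(cutoffs)) {
      r <- rle(vals < cutoffs[k])
      counts[k] <- counts[k] + sum(r$values & r$lengths >= min_cpgs)
    }
  }
  counts
}

#' Call low-methylated segments from a smoothed track
#'
#' Maximal runs of consecutive CpGs with smoothed ratio strictly below
#' `m_cutoff` become segments; runs with fewer than `min_cpgs_segment` CpGs
#' are discarded. Each segment spans its first to last CpG (0-based
#' half-open, end = last 1-based position) and records its CpG count and
#' the mean of the *unsmoothed* ratios.
#'
#' @param smoothed A track with a `smoothed` column
#'   (from [smooth_methylation()]).
#' @param config A [segmentation_config()].
#' @return An interval tibble with `segment_class` (from
#'   [classify_segments()]), `n_cpgs` and `mean_methylation`.
#' @export
segment_low_methylated <- function(smoothed, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  out <- purrr::map_dfr(split(smoothed, smoothed$chrom), function(tr) {
    tr <- dplyr::arrange(tr, .data$pos)
    r <- rle(tr$smoothed < config$m_cutoff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= config$min_cpgs_segment
    if (!any(keep)) return(NULL)
    purrr::map2_dfr(starts[keep], ends[keep], function(a, b) {
      tibble::tibble(
        chrom = tr$chrom[1],
        start = tr$pos[a] - 1L,
        end = tr$pos[b],
        n_cpgs = b - a + 1L,
        mean_methylation = mean(tr$ratio[a:b])
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          n_cpgs = integer(), mean_methylation = double())
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  classify_segments(out, config$umr_cpg_threshold)
}

#' Classify segments as LMR or UMR by CpG count
#'
#' @param intervals An interval tibble with an `n_cpgs` column.
#' @param umr_cpg_threshold Segments with `n_cpgs >=` this are UMR,
#'   otherwise LMR (default 30).
#' @return `intervals` with a `segment_class` column.
#' @export
classify_segments <- function(intervals, umr_cpg_threshold = 30) {
  intervals$segment_class <- ifelse(intervals$n_cpgs >= umr_cpg_threshold,
                                    "UMR", "LMR")
  dplyr::relocate(intervals, "segment_class", .after = "end")
}

#' Calibrate the segmentation cutoff by a shuffle-null FDR
#'
#' For each candidate cutoff m on a grid (0.1 to 0.9 in steps of 0.1), the
#' false-discovery proportion is estimated as the mean segment count over
#' `null_shuffles` methylomes — ratios permuted across CpG positions within
#' each chromosome, preserving CpG spacing — divided by the observed
#' segment count. The calibrated cutoff is the largest m with
#' FDR <= `fdr_target` (and at least one observed segment), which maximizes
#' sensitivity subject to the FDR constraint. If no m qualifies, or the
#' track is degenerate (all ratios identical), the configured default
#' cutoff is returned with `calibrated = FALSE`.
#'
#' @param track A coverage-filtered methylation track tibble.
#' @param config A [segmentation_config()].
#' @param cutoff_grid Candidate cutoffs (default `seq(0.1, 0.9, 0.1)`).
#' @return A list: `m_cutoff`, `calibrated` (logical), `fdr_table`
#'   (tibble with `m_cutoff`, `observed`, `null_mean`, `fdr`), and an
#'   updated `config` carrying the chosen cutoff.
#' @export
calibrate_cutoff_fdr <- function(track, config = segmentation_config(),
                                 cutoff_grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(config, "segmentation_config"))
  track <- track[!is.na(track$ratio), , drop = FALSE]
  if (nrow(track) < config$min_cpgs_segment ||
      length(unique(track$ratio)) == 1L) {
    warn("degenerate track; returning default cutoff uncalibrated")
    return(list(m_cutoff = config$m_cutoff, calibrated = FALSE,
                fdr_table = NULL, config = config))
  }
  track <- dplyr::arrange(track, .data$chrom, .data$pos)
  by_chrom <- split(track$ratio, track$chrom)
  sm <- function(lst) lapply(lst, running_mean_truncated, k = config$smooth_k)
  observed <- count_segments(sm(by_chrom), cutoff_grid, config$min_cpgs_segment)
  null_counts <- withr::with_seed(config$seed, {
    vapply(seq_len(config$null_shuffles), function(i) {
      shuffled <- lapply(by_chrom, sample)
      count_segments(sm(shuffled), cutoff_grid, config$min_cpgs_segment)
    }, numeric(length(cutoff_grid)))
  })
  null_mean <- rowMeans(matrix(null_counts, nrow = length(cutoff_grid)))
  fdr <- ifelse(observed > 0, null_mean / observed, NA_real_)
  tab <- tibble::tibble(m_cutoff = cutoff_grid, observed = observed,
                        null_mean = null_mean, fdr = fdr)
  ok <- which(!is.na(fdr) & fdr <= config$fdr_target)
  if (length(ok) == 0) {
    warn(sprintf("no cutoff reaches FDR <= %.3g; returning default %.2f uncalibrated",
                 config$fdr_target, config$m_cutoff))
    return(list(m_cutoff = config$m_cutoff, calibrated = FALSE,
                fdr_table = tab, config = config))
  }
  m_star <- cutoff_grid[max(ok)]
  config$m_cutoff <- m_star
  list(m_cutoff = m_star, calibrated = TRUE, fdr_table = tab, config = config)
}

#' Call LMR/UMR segments from a raw track
#'
#' Convenience wrapper: coverage filter, optional FDR calibration of the
#' cutoff, smoothing, segmentation, classification.
#'
#' @param track A methylation track tibble (strand-combined recommended).
#' @param config A [segmentation_config()].
#' @param min_coverage Minimum total reads per CpG (default 3).
#' @param calibrate Calibrate the cutoff by shuffle-null FDR? Default `TRUE`.
#' @return A list: `segments` (interval tibble), `config` (as used),
#'   `calibration` (from [calibrate_cutoff_fdr()], or `NULL`).
#' @export
call_lmrs <- function(track, config = segmentation_config(),
                      min_coverage = 3, calibrate = TRUE) {
  track <- filter_by_coverage(track, min_coverage)
  calibration <- NULL
  if (calibrate) {
    calibration <- calibrate_cutoff_fdr(track, config)
    config <- calibration$config
  }
  smoothed <- smooth_methylation(track, config$smooth_k)
  segments <- segment_low_methylated(smoothed, config)
  list(segments = segments, config = config, calibration = calibration)
}

#' Pool interval sets across samples or tissues
#'
#' Union of the input sets with overlapping and book-ended (adjacent)
#' intervals merged. Per-segment CpG counts and means are reset to `NA`,
#' to be refilled per sample by [interval_methylation()]. Idempotent and
#' commutative.
#'
#' @param sets A list of interval tibbles (a single tibble is also
#'   accepted).
#' @return A sorted, non-overlapping interval tibble.
#' @export
pool_interval_sets <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          segment_class = character(), n_cpgs = integer(),
                          mean_methylation = double())
  sets <- purrr::keep(sets, ~ nrow(.x) > 0)
  if (length(sets) == 0) return(empty)
  all <- dplyr::bind_rows(purrr::map(sets, ~ dplyr::select(.x, "chrom", "start", "end")))
  purrr::map_dfr(split(all, all$chrom), function(d) {
    # 0-based half-open -> IRanges 1-based closed; book-ended intervals
    # become adjacent and are merged by reduce()
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    tibble::tibble(
      chrom = d$chrom[1],
      start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir),
      segment_class = "generic",
      n_cpgs = NA_integer_,
      mean_methylation = NA_real_
    )
  }) %>%
    dplyr::arrange(.data$chrom, .data$start)
}
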