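#' Differential methylation of features between two groups
#'
#' Compares per-feature group means of raw methylation values between two
#' sample groups and calls a feature differentially methylated when the
#' mean difference (B minus A) strictly exceeds `min_diff` in magnitude
#' (the standard call at a ratio difference > 0.1).
#'
#' @param mat_a,mat_b Raw feature matrix tibbles (same feature columns) for
#'   groups A and B.
#' @param min_diff Minimum absolute mean ratio difference for a call
#'   (default 0.1, strict `>`).
#' @return A tibble `feature`, `mean_A`, `mean_B`, `difference`
#'   (= B - A), `call` in `{hyper_in_B, hypo_in_B, unchanged}`, with a
#'   `counts` attribute tabulating the calls.
#' @export
differential_intervals <- function(mat_a, mat_b, min_diff = 0.1) {
  Xa <- mat_to_X(mat_a)
  Xb <- mat_to_X(mat_b)
  if (nrow(Xa) == 0 || nrow(Xb) == 0) abort("both groups must be non-empty")
  common <- intersect(colnames(Xa), colnames(Xb))
  if (length(common) == 0) abort("groups share no features")
  ma <- colMeans(Xa[, common, drop = FALSE])
  mb <- colMeans(Xb[, common, drop = FALSE])
  d <- mb - ma
  # strict threshold with a representation guard: a difference equal to
  # min_diff up to double rounding is "unchanged"
  eps <- 1e-9
  call <- dplyr::case_when(d > min_diff + eps ~ "hyper_in_B",
                           d < -(min_diff + eps) ~ "hypo_in_B",
                           TRUE ~ "unchanged")
  out <- tibble::tibble(feature = common, mean_A = unname(ma),
                        mean_B = unname(mb), difference = unname(d),
                        call = call)
  attr(out, "counts") <- c(hyper_in_B = sum(call == "hyper_in_B"),
                           hypo_in_B = sum(call == "hypo_in_B"),
                           unchanged = sum(call == "unchanged"))
  out
}

#' Epigenetic age acceleration
#'
#' Predicts epigenetic age for each sample and reports the acceleration
#' delta = predicted minus chronological age. Positive deltas indicate a
#' faster-running methylation clock (poorer health under the
#' inflammation-acceleration interpretation).
#'
#' @param model A `chick_clock`.
#' @param newdata Raw feature matrix tibble for the samples to assess.
#' @param metadata Sample sheet with `tissue`, `age_days` and `group`.
#' @return A tibble `sample_id`, `tissue`, `age_days`, `group`,
#'   `predicted_age`, `delta`.
#' @export
age_acceleration <- function(model, newdata, metadata) {
  if (!"age_days" %in% names(metadata)) abort("metadata needs age_days")
  p <- predict_age(model, newdata, metadata)
  if (!"group" %in% names(p)) p$group <- "all"
  dplyr::transmute(p, .data$sample_id, .data$tissue, .data$age_days,
                   .data$group, .data$predicted_age,
                   delta = .data$predicted_age - .data$age_days)
}

#' Test group age acceleration against a reference group
#'
#' Welch two-sample t-tests of the acceleration deltas of each group
#' against the reference group (two-sided by default; set
#' `two_sided = FALSE` for the one-sided test of *greater* acceleration).
#' Groups with fewer than two samples get an undefined p-value and are
#' flagged.
#'
#' @param results An acceleration tibble from [age_acceleration()] (needs
#'   `delta` and a grouping column).
#' @param reference_group Value of `group_col` identifying the reference.
#' @param two_sided Two-sided test? Default `TRUE`.
#' @param group_col Grouping column name (default `"group"`).
#' @return A tibble `group`, `n`, `mean_delta`, `sd_delta`, `statistic`,
#'   `p_value`, `significant` (p < 0.05), `undefined`.
#' @export
test_group_acceleration <- function(results, reference_group,
                                    two_sided = TRUE, group_col = "group") {
  groups <- results[[group_col]]
  ref <- results$delta[groups == reference_group]
  if (length(ref) == 0) abort(sprintf("reference group '%s' is empty", reference_group))
  alternative <- if (two_sided) "two.sided" else "greater"
  purrr::map_dfr(setdiff(unique(groups), reference_group), function(g) {
    x <- results$delta[groups == g]
    und <- length(x) < 2 || length(ref) < 2
    if (und) {
      stat <- NA_real_; p <- NA_real_
    } else {
      tt <- t.test(x, ref, alternative = alternative, var.equal = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    tibble::tibble(group = g, n = length(x), mean_delta = mean(x),
                   sd_delta = sd(x), statistic = stat, p_value = p,
                   significant = !und && p < 0.05, undefined = und)
  })
}

#' Enrichment of clock markers in genomic features
#'
#' For each annotation label, the fraction of markers assigned to that
#' feature class divided by the fraction of the genome the class occupies:
#' enrichment(label) = (markers in label / markers) / (label bp / genome bp).
#' Interval markers are assigned by their midpoint; CpG markers by
#' position. Promoter annotations are conventionally the 1000 bp upstream
#' of the transcription start site.
#'
#' @param markers A tibble of marker intervals (`chrom`, `start`, `end`) or
#'   CpG sites (`chrom`, `pos`).
#' @param annotation A labeled interval tibble (`chrom`, `start`, `end`,
#'   `label`), disjoint or resolved by first-match precedence in row order.
#' @param genome_size Total genome size in bp.
#' @param feature_sizes Named numeric vector of total bp per label.
#' @return A tibble `label`, `n_markers`, `marker_fraction`,
#'   `genome_fraction`, `enrichment`.
#' @export
marker_feature_enrichment <- function(markers, annotation, genome_size,
                                      feature_sizes) {
  if (nrow(markers) == 0) abort("no markers supplied")
  stopifnot(all(feature_sizes <= genome_size))
  pos <- if ("pos" %in% names(markers)) {
    markers$pos
  } else {
    # midpoint of the 0-based half-open interval, as a 1-based position
    as.integer(floor((markers$start + markers$end) / 2)) + 1L
  }
  lab <- rep(NA_character_, nrow(markers))
  for (ch in unique(markers$chrom)) {
    mi <- which(markers$chrom == ch)
    ai <- which(annotation$chrom == ch)
    if (length(ai) == 0) next
    ir <- IRanges::IRanges(start = annotation$start[ai] + 1L,
                           end = annotation$end[ai])
    q <- IRanges::IRanges(start = pos[mi], width = 1L)
    hits <- IRanges::findOverlaps(q, ir, select = "first")
    lab[mi] <- annotation$label[ai][hits]
  }
  n_total <- nrow(markers)
  purrr::imap_dfr(as.list(feature_sizes), function(sz, label) {
    n <- sum(lab == label, na.rm = TRUE)
    mf <- n / n_total
    gf <- sz / genome_size
    tibble::tibble(label = label, n_markers = n, marker_fraction = mf,
                   genome_fraction = gf, enrichment = mf / gf)
  })
}

#' PCA of a methylation matrix with per-component age correlation
#'
#' Column-centered principal component analysis (via SVD) of the feature
#' matrix, reporting component scores, explained-variance fractions, and
#' the Pearson correlation of each score vector with chronological age —
#' the diagnostic that motivates the tissue-offset normalization (an
#' age-correlated component with tissue-specific offsets).
#'
#' @param mat A feature matrix tibble (raw or normalized).
#' @param metadata Sample sheet with `age_days` (and `tissue`, carried
#'   through to the scores).
#' @return A list: `scores` (tibble `sample_id`, `tissue`, `age_days`,
#'   `PC1`, ...), `variance_fraction`, `age_correlation` (tibble
#'   `component`, `r`; `NA` for zero-variance components), and the
#'   underlying `prcomp` object.
#' @export
pca_with_age_correlation <- function(mat, metadata) {
  X <- mat_to_X(mat)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  meta <- metadata[match(rownames(X), metadata$sample_id), ]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(nrow(X), ncol(X))
  scores <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
  sdev <- pc$sdev
  var_frac <- sdev^2 / sum(sdev^2)
  r <- vapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]
    if (sd(s) == 0 || sd(meta$age_days) == 0) NA_real_ else cor(s, meta$age_days)
  }, numeric(1))
  list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(X),
                     tissue = meta$tissue, age_days = meta$age_days),
      tibble::as_tibble(scores)),
    variance_fraction = var_frac[seq_len(ncol(scores))],
    age_correlation = tibble::tibble(component = colnames(scores), r = r),
    prcomp = pc
  )
}

#' Wilcoxon rank-sum comparison of two methylation distributions
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test with normal approximation,
#' tie correction and continuity correction — the test used for
#' tissue-contrast comparisons of feature methylation distributions.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @return A tibble `statistic` (the rank-sum U for the first sample),
#'   `p_value`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = FALSE, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}
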