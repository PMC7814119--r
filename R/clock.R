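#' Clock site-filtering configuration
#'
#' Filtering rules applied before clock training: CpGs on sex chromosomes
#' are removed (chicken females are ZW, so Z/W dosage differs between
#' sexes), CpGs at known SNP positions are removed (C/T polymorphisms mimic
#' methylation differences), and only CpGs whose per-strand read coverage
#' strictly exceeds a threshold in *every* sample are retained: > 10 for
#' the CpG-level clock, > 5 for CpGs inside LMRs for the LMR-level clock.
#'
#' @param sex_chromosomes Chromosome names to drop
#'   (default `c("Z", "W", "chrZ", "chrW")`).
#' @param snp_positions `NULL`, or a tibble of SNP locations with either a
#'   `pos` column (1-based) or `start`/`end` (BED half-open).
#' @param cpg_min_strand_cov Per-strand coverage threshold for the CpG
#'   clock (default 10, strict `>`).
#' @param lmr_min_strand_cov Per-strand coverage threshold for CpGs feeding
#'   LMR means (default 5, strict `>`).
#' @param require_all_samples Require the rule to hold in every sample?
#'   Default `TRUE`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(sex_chromosomes = c("Z", "W", "chrZ", "chrW"),
                          snp_positions = NULL,
                          cpg_min_strand_cov = 10,
                          lmr_min_strand_cov = 5,
                          require_all_samples = TRUE) {
  stopifnot(cpg_min_strand_cov >= 0, lmr_min_strand_cov >= 0)
  structure(list(sex_chromosomes = sex_chromosomes,
                 snp_positions = snp_positions,
                 cpg_min_strand_cov = cpg_min_strand_cov,
                 lmr_min_strand_cov = lmr_min_strand_cov,
                 require_all_samples = require_all_samples),
            class = "filter_config")
}

snp_position_keys <- function(snp_positions) {
  if (is.null(snp_positions) || nrow(snp_positions) == 0) return(character())
  if ("pos" %in% names(snp_positions)) {
    paste(snp_positions$chrom, snp_positions$pos)
  } else {
    unlist(purrr::map2(
      seq_len(nrow(snp_positions)), snp_positions$chrom,
      function(i, ch) paste(ch, (snp_positions$start[i] + 1L):snp_positions$end[i])
    ))
  }
}

# numeric (chrom, pos, strand) key encoding: exact in doubles for
# pos < 2^32 and a few thousand chromosomes
encode_strand_keys <- function(chrom, pos, strand, chrom_levels) {
  ci <- match(chrom, chrom_levels) - 1
  (ci * 2 + (strand == "-")) * 2^32 + pos
}

# strand-resolved record keys passing the sex/SNP filters with
# total_count > threshold in every sample; returns the numeric keys plus
# the chromosome level table used for the encoding
retained_strand_keys <- function(tracks, min_strand_cov, config) {
  chrom_levels <- sort(unique(unlist(lapply(tracks, function(tr) unique(tr$chrom)))))
  snp_keys <- snp_position_keys(config$snp_positions)
  keysets <- purrr::map(tracks, function(tr) {
    keep <- !(tr$chrom %in% config$sex_chromosomes) &
      tr$total_count > min_strand_cov
    tr <- tr[keep, , drop = FALSE]
    if (length(snp_keys) > 0) {
      tr <- tr[!(paste(tr$chrom, tr$pos) %in% snp_keys), , drop = FALSE]
    }
    encode_strand_keys(tr$chrom, tr$pos, tr$strand, chrom_levels)
  })
  keys <- if (config$require_all_samples) {
    Reduce(intersect, keysets)
  } else {
    unique(unlist(keysets))
  }
  list(keys = keys, chrom_levels = chrom_levels)
}

#' Select CpG sites eligible for clock training
#'
#' Applies the sex-chromosome, SNP and per-strand coverage rules of a
#' [filter_config()] across all samples and returns the retained CpG dyads
#' (both strands must pass the coverage rule).
#'
#' @param tracks Named list of strand-resolved methylation track tibbles
#'   (names = sample ids).
#' @param config A [filter_config()].
#' @return A tibble `chrom`, `pos` of retained dyad anchor positions
#'   (plus-strand coordinate).
#' @export
filter_clock_sites <- function(tracks, config = filter_config()) {
  rk <- retained_strand_keys(tracks, config$cpg_min_strand_cov, config)
  if (length(rk$keys) == 0) {
    abort(paste("no CpG passes the clock filters in every sample;",
                "consider relaxing cpg_min_strand_cov"))
  }
  pos <- as.integer(rk$keys %% 2^32)
  idx <- rk$keys %/% 2^32
  minus <- idx %% 2 == 1
  d <- tibble::tibble(chrom = rk$chrom_levels[idx %/% 2 + 1], pos = pos,
                      strand = ifelse(minus, "-", "+"))
  anchor <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
  both <- tibble::tibble(chrom = d$chrom, anchor = anchor, strand = d$strand) %>%
    dplyr::distinct() %>%
    dplyr::count(.data$chrom, .data$anchor) %>%
    dplyr::filter(.data$n == 2L)
  if (nrow(both) == 0) {
    abort(paste("no CpG dyad has both strands covered above the threshold",
                "in every sample; consider relaxing cpg_min_strand_cov"))
  }
  dplyr::transmute(both, chrom = .data$chrom, pos = .data$anchor) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

feature_id_lmr <- function(intervals) {
  sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
}

#' Build the samples-by-features methylation matrix
#'
#' For LMR features, each value is the unweighted mean methylation ratio of
#' the retained CpGs inside the interval (strand-resolved CpGs with
#' per-strand coverage > `lmr_min_strand_cov` in every sample, after
#' sex-chromosome and SNP removal). For CpG features, each value is the
#' strand-combined methylation ratio of a retained dyad
#' (per [filter_clock_sites()]). Features not measurable in every sample
#' are dropped, so the returned matrix has no missing entries.
#'
#' @param tracks Named list of strand-resolved methylation track tibbles.
#' @param metadata Sample sheet tibble (`sample_id`, `tissue`, `age_days`,
#'   optionally `group`); every sample must have a track.
#' @param features An interval tibble (LMR mode) or a CpG site tibble with
#'   `chrom`, `pos` (CpG mode; if omitted the sites are derived via
#'   [filter_clock_sites()]).
#' @param config A [filter_config()].
#' @return A tibble with `sample_id` and one column per feature
#'   (`chrom:start-end` for LMRs, `chrom:pos` for CpGs), with attributes
#'   `feature_kind` and `is_normalized = FALSE`.
#' @export
build_feature_matrix <- function(tracks, metadata, features,
                                 config = filter_config()) {
  missing_tracks <- setdiff(metadata$sample_id, names(tracks))
  if (length(missing_tracks) > 0) {
    abort(sprintf("no track for sample(s): %s",
                  paste(missing_tracks, collapse = ", ")))
  }
  tracks <- tracks[metadata$sample_id]
  lmr_mode <- all(c("start", "end") %in% names(features))

  if (lmr_mode) {
    rk <- retained_strand_keys(tracks, config$lmr_min_strand_cov, config)
    rows <- purrr::imap(tracks, function(tr, sid) {
      k <- encode_strand_keys(tr$chrom, tr$pos, tr$strand, rk$chrom_levels)
      tr <- tr[k %in% rk$keys, , drop = FALSE]
      iv <- interval_methylation(tr, features)
      setNames(iv$mean_methylation, feature_id_lmr(iv))
    })
    kind <- "LMR"
  } else {
    sites <- if ("pos" %in% names(features)) features else filter_clock_sites(tracks, config)
    site_id <- sprintf("%s:%d", sites$chrom, sites$pos)
    rows <- purrr::map(tracks, function(tr) {
      agg <- aggregate_strands(tr)
      v <- setNames(agg$ratio, sprintf("%s:%d", agg$chrom, agg$pos))
      setNames(v[site_id], site_id)
    })
    kind <- "CpG"
  }

  values <- do.call(rbind, rows)
  complete <- colSums(is.na(values)) == 0
  if (!any(complete)) {
    abort("no feature is measurable in every sample; relax the coverage rules")
  }
  values <- values[, complete, drop = FALSE]
  out <- tibble::as_tibble(values)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = metadata$sample_id), out)
  attr(out, "feature_kind") <- kind
  attr(out, "is_normalized") <- FALSE
  out
}

mat_to_X <- function(mat) {
  X <- as.matrix(mat[, setdiff(names(mat), "sample_id"), drop = FALSE])
  rownames(X) <- mat$sample_id
  X
}

X_to_mat <- function(X) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(X)), tibble::as_tibble(X))
}

#' Tissue-offset normalization of a methylation matrix
#'
#' For every feature, the mean value over all training samples of the same
#' tissue is subtracted (the per-tissue "offset"). This removes the
#' tissue-maturation offset visible in the principal components of LMR
#' methylation, putting all tissues on a shared age axis. The offsets (and
#' per-feature global means, used as a fallback for tissues unseen at
#' prediction time) are returned for reuse.
#'
#' @param mat A raw feature matrix tibble (from [build_feature_matrix()]).
#' @param metadata Sample sheet covering all rows of `mat`.
#' @return A `meth_norm` list: `values` (normalized matrix tibble),
#'   `offsets` (long tibble `tissue`, `feature`, `offset`), `fallback`
#'   (tibble `feature`, `offset` of global training means), `feature_kind`.
#' @export
tissue_normalize <- function(mat, metadata) {
  X <- mat_to_X(mat)
  meta <- metadata[match(rownames(X), metadata$sample_id), ]
  if (anyNA(meta$tissue)) abort("every sample needs a tissue label")
  tissues <- unique(meta$tissue)
  offs <- lapply(tissues, function(tt) {
    colMeans(X[meta$tissue == tt, , drop = FALSE])
  })
  names(offs) <- tissues
  Xn <- X
  for (tt in tissues) {
    rows <- meta$tissue == tt
    Xn[rows, ] <- sweep(X[rows, , drop = FALSE], 2, offs[[tt]], "-")
  }
  offsets <- purrr::imap_dfr(offs, function(v, tt) {
    tibble::tibble(tissue = tt, feature = colnames(X), offset = unname(v))
  })
  structure(list(
    values = X_to_mat(Xn),
    offsets = offsets,
    fallback = tibble::tibble(feature = colnames(X), offset = colMeans(X)),
    feature_kind = attr(mat, "feature_kind") %||% "LMR"
  ), class = "meth_norm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an elastic-net DNA methylation clock
#'
#' Regresses chronological age (days) on tissue-normalized methylation
#' values: the penalty is selected by [select_lambda_cv()] and the final
#' elastic-net fit at that penalty defines the clock. The mixing parameter
#' defaults to `alpha = 0.9` for LMR clocks (use 0.7 for CpG clocks), the
#' values at which the fit is close to the best while keeping a manageable
#' marker count.
#'
#' @param normalized A `meth_norm` object from [tissue_normalize()].
#' @param metadata Sample sheet with `age_days` for all samples.
#' @param alpha Elastic-net mixing parameter (default 0.9).
#' @param k_folds Folds for penalty selection (default 10).
#' @param seed Integer seed for the penalty-selection folds.
#' @param lambda_grid Optional penalty grid.
#' @param one_se Use the one-standard-error rule for the penalty? Default
#'   `FALSE`.
#' @return A `chick_clock` object: selected features with weights,
#'   intercept, `alpha`, `lambda`, stored per-tissue offsets and fallback
#'   offsets, and training metadata.
#' @export
train_clock <- function(normalized, metadata, alpha = 0.9, k_folds = 10,
                        seed = 1L, lambda_grid = NULL, one_se = FALSE) {
  stopifnot(inherits(normalized, "meth_norm"))
  mat <- normalized$values
  X <- mat_to_X(mat)
  meta <- metadata[match(rownames(X), metadata$sample_id), ]
  y <- meta$age_days
  sel <- select_lambda_cv(X, y, alpha, lambda_grid = lambda_grid,
                          k_folds = k_folds, seed = seed, one_se = one_se)
  fit <- fit_elastic_net(X, y, alpha, sel$lambda)
  nz <- which(fit$beta != 0)
  if (length(nz) == 0) {
    warn("no feature received a nonzero weight; returning an intercept-only clock")
  }
  feats <- colnames(X)[nz]
  structure(list(
    schema_version = "1.0",
    feature_kind = normalized$feature_kind,
    weights = setNames(fit$beta[nz], feats),
    intercept = fit$intercept,
    alpha = alpha,
    lambda = sel$lambda,
    tissue_offsets = dplyr::filter(normalized$offsets, .data$feature %in% feats),
    fallback_offsets = setNames(
      normalized$fallback$offset[match(feats, normalized$fallback$feature)], feats),
    training = list(n = nrow(X), seed = seed, k_folds = k_folds,
                    cv_rmse = min(sel$cv_curve$rmse),
                    n_features_considered = ncol(X))
  ), class = "chick_clock")
}

#' @export
print.chick_clock <- function(x, ...) {
  cat(sprintf("<chick_clock> %s clock: %d feature(s), alpha = %g, lambda = %.4g\n",
              x$feature_kind, length(x$weights), x$alpha, x$lambda))
  cat(sprintf("  trained on %d samples; penalty-selection CV RMSE %.2f days\n",
              x$training$n, x$training$cv_rmse))
  invisible(x)
}

#' Predict epigenetic age
#'
#' Applies a trained clock to raw feature values:
#' \eqn{\hat y = \beta_0 + \sum_j \beta_j (x_j - \mathrm{offset}(tissue, j))}.
#' Tissues unseen during training fall back to the global training feature
#' means (with a warning). The prediction is not clamped.
#'
#' @param model A `chick_clock`.
#' @param newdata Tibble with `sample_id` and raw feature columns covering
#'   all model features (missing features are an error).
#' @param metadata Sample sheet providing `tissue` (and optionally
#'   `age_days`, `group`) per sample; alternatively `newdata` may carry a
#'   `tissue` column.
#' @return A tibble `sample_id`, `tissue`, `predicted_age` (days), joined
#'   with `age_days`/`group` when available.
#' @export
predict_age <- function(model, newdata, metadata = NULL) {
  stopifnot(inherits(model, "chick_clock"))
  feats <- names(model$weights)
  missing_feats <- setdiff(feats, names(newdata))
  if (length(missing_feats) > 0) {
    abort(sprintf("sample data lacks %d model feature(s): %s",
                  length(missing_feats),
                  paste(head(missing_feats, 5), collapse = ", ")))
  }
  if (!is.null(metadata)) {
    meta <- metadata[match(newdata$sample_id, metadata$sample_id), ]
    tissue <- meta$tissue
  } else if ("tissue" %in% names(newdata)) {
    tissue <- newdata$tissue
    meta <- NULL
  } else {
    abort("provide `metadata` or a `tissue` column in `newdata`")
  }
  off_wide <- tidyr::pivot_wider(model$tissue_offsets, names_from = "feature",
                                 values_from = "offset")
  known <- tissue %in% off_wide$tissue
  if (any(!known)) {
    warn(sprintf("unknown tissue(s) %s: using global fallback offsets",
                 paste(unique(tissue[!known]), collapse = ", ")))
  }
  Xraw <- as.matrix(newdata[, feats, drop = FALSE])
  offmat <- matrix(rep(model$fallback_offsets[feats], each = nrow(Xraw)),
                   nrow = nrow(Xraw))
  if (any(known) && length(feats) > 0) {
    idx <- match(tissue[known], off_wide$tissue)
    offmat[known, ] <- as.matrix(off_wide[idx, feats, drop = FALSE])
  }
  pred <- model$intercept + drop((Xraw - offmat) %*% model$weights)
  out <- tibble::tibble(sample_id = newdata$sample_id, tissue = tissue,
                        predicted_age = pred)
  if (!is.null(metadata)) {
    extra <- intersect(c("age_days", "group"), names(metadata))
    out <- dplyr::left_join(out, metadata[, c("sample_id", extra)], by = "sample_id")
  }
  out
}

# seeded fold assignment stratified by (tissue, age group); computed on the
# sample_id-sorted view so the split is invariant to row order
stratified_folds <- function(metadata, k_folds, seed) {
  ord <- order(metadata$sample_id)
  key <- paste(metadata$tissue, metadata$age_days)[ord]
  fold_ord <- integer(length(ord))
  withr::with_seed(seed, {
    for (idx in split(seq_along(ord), key)) {
      labels <- rep(sample(seq_len(k_folds)), length.out = length(idx))
      fold_ord[idx[sample.int(length(idx))]] <- labels
    }
  })
  fold <- integer(length(ord))
  fold[ord] <- fold_ord
  fold
}

#' Cross-validate a methylation clock
#'
#' K-fold cross-validation of the full training procedure. Folds are
#' stratified by (tissue, age group) and seeded. By default
#' (`normalize = "fold"`), tissue offsets and the penalty are re-estimated
#' on each fold's training split only, so no information leaks from the
#' held-out samples; `normalize = "full"` instead normalizes once on the
#' complete matrix before splitting (the single-normalization variant).
#' The reported RMSE is over all out-of-fold predictions pooled.
#'
#' @param mat A *raw* feature matrix tibble.
#' @param metadata Sample sheet with `tissue` and `age_days`.
#' @param alpha Elastic-net mixing parameter (default 0.9).
#' @param k_folds Number of outer folds (default 6).
#' @param seed Integer seed (required; drives fold assignment and inner
#'   penalty selection).
#' @param normalize `"fold"` (default) or `"full"`, see above.
#' @param inner_folds Folds for the inner penalty selection (default 5).
#' @param lambda_grid Optional penalty grid shared across folds.
#' @return A `chick_clock_cv` object: `predictions` (tibble `sample_id`,
#'   `tissue`, `age_days`, `fold`, `predicted_age`), `rmse` (days),
#'   `alpha`, `k_folds`, `seed`, `normalize`, `fold_lambda`.
#' @export
cross_validate_clock <- function(mat, metadata, alpha = 0.9, k_folds = 6,
                                 seed = 1L, normalize = c("fold", "full"),
                                 inner_folds = 5, lambda_grid = NULL) {
  normalize <- match.arg(normalize)
  # canonical sample order so results do not depend on input row order
  mat <- mat[order(mat$sample_id), , drop = FALSE]
  meta <- metadata[match(mat$sample_id, metadata$sample_id), ]
  stopifnot(nrow(mat) >= k_folds)
  fold <- stratified_folds(meta, k_folds, seed)
  if (normalize == "full") {
    norm_full <- tissue_normalize(mat, meta)
  }
  preds <- vector("list", k_folds)
  fold_lambda <- rep(NA_real_, k_folds)
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (!any(!tr)) next
    mtr <- mat[tr, , drop = FALSE]
    mte <- mat[!tr, , drop = FALSE]
    attr(mtr, "feature_kind") <- attr(mat, "feature_kind")
    if (normalize == "fold") {
      norm <- tissue_normalize(mtr, meta[tr, ])
    } else {
      norm <- norm_full
      norm$values <- norm_full$values[tr, , drop = FALSE]
    }
    model <- suppressWarnings(train_clock(
      norm, meta[tr, ], alpha = alpha, k_folds = inner_folds,
      seed = seed + 1000L * k, lambda_grid = lambda_grid))
    fold_lambda[k] <- model$lambda
    p <- suppressWarnings(predict_age(model, mte, meta[!tr, ]))
    p$fold <- k
    preds[[k]] <- p
  }
  predictions <- dplyr::bind_rows(preds)
  rmse <- sqrt(mean((predictions$predicted_age - predictions$age_days)^2))
  structure(list(predictions = predictions, rmse = rmse, alpha = alpha,
                 k_folds = k_folds, seed = seed, normalize = normalize,
                 fold_lambda = fold_lambda),
            class = "chick_clock_cv")
}

#' @export
print.chick_clock_cv <- function(x, ...) {
  cat(sprintf("<chick_clock_cv> %d-fold CV (alpha = %g, %s normalization): RMSE %.2f days over %d samples\n",
              x$k_folds, x$alpha, x$normalize, x$rmse, nrow(x$predictions)))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

num_to_str <- function(x) sprintf("%.17g", x)
named_num_to_str <- function(x) as.list(setNames(num_to_str(x), names(x)))

#' Serialize / restore a clock model as JSON
#'
#' Weights and offsets are encoded as decimal strings with 17 significant
#' digits, so models round-trip bit-exactly. Files with a different schema
#' version are rejected.
#'
#' @param model A `chick_clock`.
#' @param path JSON file path.
#' @return `write_clock()`: `path` invisibly; `read_clock()`: the restored
#'   `chick_clock`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "chick_clock"))
  offsets <- split(model$tissue_offsets, model$tissue_offsets$tissue)
  offsets <- lapply(offsets, function(d) as.list(setNames(num_to_str(d$offset), d$feature)))
  payload <- list(
    schema_version = model$schema_version,
    feature_kind = model$feature_kind,
    alpha = model$alpha,
    lambda = num_to_str(model$lambda),
    intercept = num_to_str(model$intercept),
    weights = named_num_to_str(model$weights),
    offsets = offsets,
    fallback_offsets = named_num_to_str(model$fallback_offsets),
    training = list(n = model$training$n, seed = model$training$seed,
                    k_folds = model$training$k_folds,
                    cv_rmse = num_to_str(model$training$cv_rmse),
                    n_features_considered = model$training$n_features_considered)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema_version, "1.0")) {
    abort(sprintf("unsupported clock schema version: %s",
                  payload$schema_version %||% "<missing>"))
  }
  to_num <- function(l) setNames(as.numeric(unlist(l)), names(l))
  offsets <- purrr::imap_dfr(payload$offsets, function(l, tt) {
    tibble::tibble(tissue = tt, feature = names(l), offset = as.numeric(unlist(l)))
  })
  structure(list(
    schema_version = payload$schema_version,
    feature_kind = payload$feature_kind,
    weights = to_num(payload$weights),
    intercept = as.numeric(payload$intercept),
    alpha = payload$alpha,
    lambda = as.numeric(payload$lambda),
    tissue_offsets = offsets,
    fallback_offsets = to_num(payload$fallback_offsets),
    training = list(n = payload$training$n, seed = payload$training$seed,
                    k_folds = payload$training$k_folds,
                    cv_rmse = as.numeric(payload$training$cv_rmse),
                    n_features_considered = payload$training$n_features_considered)
  ), class = "chick_clock")
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a fitted clock
#'
#' @param x A `chick_clock`.
#' @param ... Unused.
#' @return A tibble `feature`, `weight`, sorted by `|weight|` descending.
#' @export
tidy.chick_clock <- function(x, ...) {
  tibble::tibble(feature = names(x$weights), weight = unname(x$weights)) %>%
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @rdname tidy.chick_clock
#' @export
glance.chick_clock <- function(x, ...) {
  tibble::tibble(feature_kind = x$feature_kind, alpha = x$alpha,
                 lambda = x$lambda, n_features = length(x$weights),
                 n_train = x$training$n, cv_rmse = x$training$cv_rmse)
}

#' Tidy cross-validation results
#'
#' @param x A `chick_clock_cv`.
#' @param ... Unused.
#' @return `tidy()`: the out-of-fold predictions; `glance()`: a one-row
#'   summary with the pooled RMSE.
#' @export
tidy.chick_clock_cv <- function(x, ...) x$predictions

#' @rdname tidy.chick_clock_cv
#' @export
glance.chick_clock_cv <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, alpha = x$alpha, k_folds = x$k_folds,
                 n = nrow(x$predictions), normalize = x$normalize)
}
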