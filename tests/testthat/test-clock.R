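# two-sample toy cohort used across several tests
toy_tracks <- function() {
  mk <- function(meths) {
    make_track("chr1", c(100, 101, 200, 201, 300, 301),
               rep(c("+", "-"), 3), meth = meths, total = 20)
  }
  list(s1 = mk(c(2, 2, 10, 10, 18, 18)),
       s2 = mk(c(4, 4, 12, 12, 16, 16)))
}

toy_meta <- function() {
  tibble::tibble(sample_id = c("s1", "s2"), tissue = c("jejunum", "jejunum"),
                 age_days = c(14, 28), group = "control")
}

test_that("clock site filters drop sex chromosomes, SNPs and low-coverage CpGs", {
  tracks <- toy_tracks()
  # add a sex-chromosome CpG and a SNP-flagged CpG to both samples
  extra <- function(tr) {
    dplyr::bind_rows(tr,
      make_track("chrZ", c(50, 51), c("+", "-"), meth = 5, total = 20),
      make_track("chr1", c(400, 401), c("+", "-"), meth = 5, total = 20))
  }
  tracks <- lapply(tracks, extra)
  snps <- tibble::tibble(chrom = "chr1", pos = 400L)
  sites <- filter_clock_sites(tracks, filter_config(snp_positions = snps,
                                                    cpg_min_strand_cov = 10))
  expect_equal(sites$pos, c(100L, 200L, 300L))
  expect_false(any(sites$chrom == "chrZ"))

  # one dyad failing coverage in one sample is dropped everywhere
  tracks2 <- toy_tracks()
  tracks2$s2$total_count[tracks2$s2$pos == 200] <- 8L
  sites2 <- filter_clock_sites(tracks2, filter_config(cpg_min_strand_cov = 10))
  expect_equal(sites2$pos, c(100L, 300L))

  expect_error(filter_clock_sites(tracks2, filter_config(cpg_min_strand_cov = 100)),
               "relaxing")
})

test_that("feature matrices are complete, per-kind, and drop unmeasurable features", {
  tracks <- toy_tracks()
  meta <- toy_meta()
  lmrs <- interval_tbl("chr1", c(90, 190, 290), c(110, 210, 310))

  mat <- build_feature_matrix(tracks, meta, lmrs, filter_config())
  expect_equal(dim(mat), c(2, 4))
  expect_equal(attr(mat, "feature_kind"), "LMR")
  expect_equal(unname(unlist(mat[1, -1])), c(0.1, 0.5, 0.9))

  # an LMR under-covered in one sample disappears for all samples
  tracks$s2$total_count[tracks$s2$pos %in% c(200, 201)] <- 4L
  mat2 <- build_feature_matrix(tracks, meta, lmrs,
                               filter_config(lmr_min_strand_cov = 5))
  expect_equal(ncol(mat2), 3)

  # CpG mode uses strand-combined dyad ratios
  cpg_mat <- build_feature_matrix(toy_tracks(), meta,
                                  tibble::tibble(chrom = "chr1", pos = c(100L, 300L)),
                                  filter_config())
  expect_equal(attr(cpg_mat, "feature_kind"), "CpG")
  expect_equal(unname(unlist(cpg_mat[1, -1])), c(4 / 40, 36 / 40))

  expect_error(build_feature_matrix(toy_tracks()["s1"], meta, lmrs),
               "no track for sample")
})

test_that("tissue normalization centers every tissue and stores reusable offsets", {
  mat <- tibble::tibble(sample_id = c("a", "b", "c"),
                        f1 = c(0.2, 0.4, 0.7), f2 = c(0.5, 0.5, 0.1))
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         tissue = c("ileum", "ileum", "spleen"),
                         age_days = c(3, 34, 15))
  norm <- tissue_normalize(mat, meta)
  expect_equal(unname(unlist(norm$values[1:2, "f1"])), c(-0.1, 0.1))
  off <- norm$offsets
  expect_equal(off$offset[off$tissue == "ileum" & off$feature == "f1"], 0.3)
  # single-sample tissue normalizes to exactly zero
  expect_equal(unname(unlist(norm$values[3, -1])), c(0, 0))

  # per-tissue per-feature means are zero to numerical precision
  for (tt in unique(meta$tissue)) {
    m <- colMeans(as.matrix(norm$values[meta$tissue == tt, -1]))
    expect_true(all(abs(m) < 1e-12))
  }

  # stored offsets apply the *training* means to held-out samples
  held <- tibble::tibble(sample_id = "d", f1 = 0.9, f2 = 0.9)
  off_f1 <- off$offset[off$tissue == "ileum" & off$feature == "f1"]
  expect_equal(0.9 - off_f1, 0.6)
})

test_that("predict_age applies the linear form with tissue offsets and fallbacks", {
  model <- structure(list(
    schema_version = "1.0", feature_kind = "LMR",
    weights = c(f1 = 2), intercept = 10, alpha = 0.9, lambda = 0.1,
    tissue_offsets = tibble::tibble(tissue = "jejunum", feature = "f1",
                                    offset = 0.25),
    fallback_offsets = c(f1 = 0.30),
    training = list(n = 10, seed = 1, k_folds = 5, cv_rmse = 1,
                    n_features_considered = 1)
  ), class = "chick_clock")

  nd <- tibble::tibble(sample_id = "s", f1 = 0.30, tissue = "jejunum")
  expect_equal(predict_age(model, nd)$predicted_age, 10 + 2 * 0.05)

  # all features at their training tissue means -> intercept
  nd0 <- tibble::tibble(sample_id = "s", f1 = 0.25, tissue = "jejunum")
  expect_equal(predict_age(model, nd0)$predicted_age, 10)

  # unknown tissue falls back to global means with a warning
  ndu <- tibble::tibble(sample_id = "s", f1 = 0.30, tissue = "liver")
  expect_warning(pu <- predict_age(model, ndu), "fallback")
  expect_equal(pu$predicted_age, 10 + 2 * 0)

  # batch equals per-sample predictions
  batch <- tibble::tibble(sample_id = c("x", "y"), f1 = c(0.1, 0.4),
                          tissue = "jejunum")
  single <- vapply(1:2, function(i)
    predict_age(model, batch[i, ])$predicted_age, numeric(1))
  expect_equal(predict_age(model, batch)$predicted_age, single)

  expect_error(predict_age(model, tibble::tibble(sample_id = "s", tissue = "jejunum")),
               "f1")
})

test_that("offsets absorb per-tissue constants: training and prediction invariant", {
  withr::with_seed(20, {
    meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                           tissue = rep(c("ileum", "spleen"), each = 6),
                           age_days = rep(c(3, 15, 34), 4))
    X <- matrix(runif(12 * 6, 0.1, 0.6), 12, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    X[, 1] <- X[, 1] + 0.01 * meta$age_days
  })
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                          tibble::as_tibble(X))
  shifted <- mat
  shifted$f1[meta$tissue == "ileum"] <- shifted$f1[meta$tissue == "ileum"] + 0.2

  m1 <- train_clock(tissue_normalize(mat, meta), meta, alpha = 0.9, k_folds = 4,
                    seed = 5)
  m2 <- train_clock(tissue_normalize(shifted, meta), meta, alpha = 0.9,
                    k_folds = 4, seed = 5)
  expect_equal(m1$weights, m2$weights)

  test_sample <- tibble::tibble(sample_id = "t", tissue = "ileum",
                                f1 = 0.5, f2 = 0.3, f3 = 0.3, f4 = 0.3,
                                f5 = 0.3, f6 = 0.3)
  test_shifted <- dplyr::mutate(test_sample, f1 = .data$f1 + 0.2)
  expect_equal(predict_age(m1, test_sample)$predicted_age,
               predict_age(m2, test_shifted)$predicted_age)
})

test_that("training recovers a sparse planted signal among many noise features", {
  withr::with_seed(21, {
    n <- 40; p <- 500
    age <- rep(c(3, 15, 34), length.out = n)
    X <- matrix(rnorm(n * p, 0, 0.03), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    planted <- 1:5
    for (j in planted) X[, j] <- X[, j] + 0.012 * age * sample(c(-1, 1), 1)
    meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           tissue = "jejunum", age_days = age)
  })
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                          tibble::as_tibble(X))
  model <- train_clock(tissue_normalize(mat, meta), meta, alpha = 0.9,
                       k_folds = 5, seed = 2)
  expect_gte(sum(paste0("f", planted) %in% names(model$weights)), 4)
})

test_that("cross-validation covers each sample once and is order-invariant", {
  withr::with_seed(22, {
    meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:24),
                           tissue = rep(c("ileum", "jejunum"), each = 12),
                           age_days = rep(rep(c(3, 15, 34), each = 4), 2))
    X <- matrix(runif(24 * 20, 0.1, 0.7), 24, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    X[, 1:4] <- X[, 1:4] + outer(0.01 * meta$age_days, rep(1, 4))
  })
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                          tibble::as_tibble(X))
  cv <- cross_validate_clock(mat, meta, alpha = 0.9, k_folds = 4, seed = 9)
  expect_setequal(cv$predictions$sample_id, meta$sample_id)
  expect_equal(nrow(cv$predictions), 24)
  expect_equal(cv$rmse,
               sqrt(mean((cv$predictions$predicted_age -
                            cv$predictions$age_days)^2)))

  perm <- withr::with_seed(1, sample(24))
  cv2 <- cross_validate_clock(mat[perm, ], meta, alpha = 0.9, k_folds = 4,
                              seed = 9)
  expect_equal(cv2$rmse, cv$rmse)

  # the leakage-free default differs from full-matrix normalization only in
  # how offsets are estimated; both must produce finite, comparable errors
  cvf <- cross_validate_clock(mat, meta, alpha = 0.9, k_folds = 4, seed = 9,
                              normalize = "full")
  expect_true(is.finite(cvf$rmse))
})

test_that("clock models round-trip bit-exactly through JSON", {
  model <- structure(list(
    schema_version = "1.0", feature_kind = "LMR",
    weights = c(f1 = 1 / 3, f2 = -sqrt(2)), intercept = exp(1),
    alpha = 0.9, lambda = pi / 10,
    tissue_offsets = tibble::tibble(tissue = c("jejunum", "jejunum", "ileum", "ileum"),
                                    feature = c("f1", "f2", "f1", "f2"),
                                    offset = c(0.1, 1 / 7, 0.2, 2 / 7)),
    fallback_offsets = c(f1 = 0.15, f2 = 3 / 14),
    training = list(n = 36, seed = 4, k_folds = 6, cv_rmse = 1.234567890123,
                    n_features_considered = 500)
  ), class = "chick_clock")
  path <- tempfile(fileext = ".json")
  write_clock(model, path)
  back <- read_clock(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$intercept, model$intercept)
  expect_identical(back$lambda, model$lambda)
  expect_identical(back$fallback_offsets, model$fallback_offsets)
  expect_identical(dplyr::arrange(back$tissue_offsets, tissue, feature),
                   dplyr::arrange(model$tissue_offsets, tissue, feature))

  nd <- tibble::tibble(sample_id = "s", f1 = 0.17, f2 = 0.05, tissue = "ileum")
  expect_identical(predict_age(model, nd)$predicted_age,
                   predict_age(back, nd)$predicted_age)

  # truncated and wrong-schema files are rejected
  txt <- readLines(path)
  trunc <- tempfile(fileext = ".json")
  writeLines(head(txt, length(txt) %/% 2), trunc)
  expect_error(read_clock(trunc))
  bad <- tempfile(fileext = ".json")
  writeLines(sub('"1.0"', '"9.9"', paste(txt, collapse = "\n")), bad)
  expect_error(read_clock(bad), "schema")
})

test_that("tidy and glance summarize clock objects", {
  model <- structure(list(
    schema_version = "1.0", feature_kind = "LMR",
    weights = c(a = 0.5, b = -2), intercept = 1, alpha = 0.9, lambda = 0.2,
    tissue_offsets = tibble::tibble(tissue = "t", feature = c("a", "b"),
                                    offset = 0),
    fallback_offsets = c(a = 0, b = 0),
    training = list(n = 12, seed = 1, k_folds = 5, cv_rmse = 2,
                    n_features_considered = 10)
  ), class = "chick_clock")
  td <- tidy(model)
  expect_equal(td$feature, c("b", "a"))  # sorted by |weight|
  gl <- glance(model)
  expect_equal(gl$n_features, 2)
  expect_equal(gl$alpha, 0.9)
})
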