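mat_from <- function(values, ids = paste0("s", seq_len(nrow(values)))) {
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(values))
}

test_that("differential calls use strict thresholds on group mean differences", {
  A <- mat_from(matrix(c(0.30, 0.30, 0.20, 0.20, 0.50, 0.50), 2,
                       dimnames = list(NULL, c("f1", "f2", "f3"))))
  B <- mat_from(matrix(c(0.45, 0.45, 0.30, 0.30, 0.50, 0.50), 2,
                       dimnames = list(NULL, c("f1", "f2", "f3"))),
                ids = c("t1", "t2"))
  got <- differential_intervals(A, B, min_diff = 0.1)
  expect_equal(got$call, c("hyper_in_B", "unchanged", "unchanged"))
  expect_equal(got$difference[1], 0.15)
  expect_equal(got$difference[2], 0.10)  # exactly at the boundary: unchanged

  same <- differential_intervals(A, A)
  expect_true(all(same$call == "unchanged"))

  expect_error(differential_intervals(A[0, ], B), "non-empty")
})

test_that("differential calling mirrors when groups swap", {
  withr::with_seed(30, {
    A <- mat_from(matrix(runif(5 * 40), 5, 40,
                         dimnames = list(NULL, paste0("f", 1:40))))
    B <- mat_from(matrix(runif(5 * 40), 5, 40,
                         dimnames = list(NULL, paste0("f", 1:40))),
                  ids = paste0("t", 1:5))
  })
  ab <- differential_intervals(A, B)
  ba <- differential_intervals(B, A)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$call == "hyper_in_B", ba$call == "hypo_in_B")
  expect_equal(sum(attr(ab, "counts")), 40)
})

test_that("age acceleration is predicted minus chronological age, grouped tests vs reference", {
  acc <- tibble::tibble(sample_id = paste0("s", 1:12),
                        tissue = "jejunum",
                        age_days = 14,
                        group = rep(c("reference", "treated", "lone"),
                                    c(6, 5, 1)),
                        predicted_age = 14 + c(rnorm(6, 0, 1e-3) + 0,
                                               rnorm(5, 0, 1e-3) + 3,
                                               0),
                        delta = NA_real_)
  acc$delta <- acc$predicted_age - acc$age_days
  got <- test_group_acceleration(acc, "reference")
  treated <- got[got$group == "treated", ]
  expect_lt(treated$p_value, 0.05)
  expect_true(treated$significant)
  expect_equal(treated$mean_delta, 3, tolerance = 0.01)
  # direct Welch oracle
  oracle <- t.test(acc$delta[acc$group == "treated"],
                   acc$delta[acc$group == "reference"])
  expect_equal(treated$p_value, oracle$p.value)
  expect_equal(treated$statistic, unname(oracle$statistic))

  lone <- got[got$group == "lone", ]
  expect_true(lone$undefined)
  expect_true(is.na(lone$p_value))

  # identical groups: p near 1
  acc2 <- acc[acc$group != "lone", ]
  acc2$delta <- rep(c(0.1, -0.1, 0.2, -0.2, 0), c(3, 3, 2, 2, 1))
  got2 <- test_group_acceleration(acc2, "reference")
  expect_gt(got2$p_value, 0.5)

  expect_error(test_group_acceleration(acc, "absent"), "empty")
})

test_that("marker enrichment equals fraction-of-markers over fraction-of-genome", {
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(0L, 50000L),
                        end = c(50000L, 1000000L),
                        label = c("promoter", "other"))
  markers <- interval_tbl("chr1", c(seq(0, 15500, by = 1000),
                                    seq(600000, 615000, by = 1000)),
                          c(seq(0, 15500, by = 1000),
                            seq(600000, 615000, by = 1000)) + 100)
  got <- marker_feature_enrichment(markers, ann, genome_size = 1e6,
                                   feature_sizes = c(promoter = 5e4,
                                                     other = 9.5e5))
  # 16 of 32 markers in promoters occupying 5% of the genome
  expect_equal(got$enrichment[got$label == "promoter"], 0.5 / 0.05)

  # enrichments weighted by genome fractions sum to 1 over a disjoint cover
  expect_equal(sum(got$enrichment * got$genome_fraction), 1)

  # a label holding no markers has enrichment 0
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(chrom = "chr2", start = 0L,
                                               end = 1000L, label = "empty"))
  got2 <- marker_feature_enrichment(markers, ann2, 1e6,
                                    c(promoter = 5e4, other = 949000,
                                      empty = 1000))
  expect_equal(got2$enrichment[got2$label == "empty"], 0)

  expect_error(marker_feature_enrichment(markers[0, ], ann, 1e6,
                                         c(promoter = 5e4)), "no markers")
})

test_that("uniform markers give enrichment near 1 within binomial error", {
  withr::with_seed(31, {
    pos <- sample.int(1e6, 4000)
  })
  markers <- tibble::tibble(chrom = "chr1", pos = pos)
  sizes <- c(promoter = 1e5, gene = 4e5, intergenic = 5e5)
  ann <- tibble::tibble(chrom = "chr1", start = c(0L, 1e5L, 5e5L),
                        end = c(1e5L, 5e5L, 1e6L),
                        label = names(sizes))
  got <- marker_feature_enrichment(markers, ann, 1e6, sizes)
  for (i in seq_len(nrow(got))) {
    p <- got$genome_fraction[i]
    se <- sqrt(p * (1 - p) / 4000) / p
    expect_lt(abs(got$enrichment[i] - 1), 4 * se)
  }
})

test_that("PCA finds an age-correlated component and reconstructs the matrix", {
  withr::with_seed(32, {
    n <- 24
    age <- rep(c(3, 15, 34), each = 8)
    X <- matrix(rnorm(n * 60, 0, 0.5), n, 60,
                dimnames = list(NULL, paste0("f", 1:60)))
    X[, 1:50] <- X[, 1:50] + outer(age, runif(50, 0.05, 0.1))
    meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           tissue = "jejunum", age_days = age)
  })
  mat <- mat_from(X, meta$sample_id)
  res <- pca_with_age_correlation(mat, meta)
  expect_gt(max(abs(res$age_correlation$r[1:2])), 0.9)
  expect_equal(sum(res$variance_fraction), 1)

  # full-rank reconstruction of the centered matrix
  pc <- res$prcomp
  Xc <- sweep(X, 2, colMeans(X), "-")
  expect_equal(unname(pc$x %*% t(pc$rotation)), unname(Xc), tolerance = 1e-8)

  # age-shuffled labels: observed top-component correlation beats the
  # 95th percentile of the permutation null
  obs <- max(abs(res$age_correlation$r[1:2]))
  perm <- withr::with_seed(33, {
    replicate(50, {
      meta_p <- meta
      meta_p$age_days <- sample(meta$age_days)
      max(abs(pca_with_age_correlation(mat, meta_p)$age_correlation$r[1:2]))
    })
  })
  expect_gt(obs, stats::quantile(perm, 0.95))
})

test_that("rank-sum test matches exact enumeration on small samples", {
  same <- rank_sum_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)

  a <- rep(0, 20); b <- rep(1, 20)
  expect_lt(rank_sum_compare(a, b)$p_value, 1e-6)

  withr::with_seed(34, {
    for (i in 1:5) {
      x <- round(rnorm(5), 1)
      y <- round(rnorm(5, 0.8), 1)
      approx_p <- rank_sum_compare(x, y)$p_value
      exact_p <- rank_sum_exact_oracle(x, y)
      expect_lt(abs(approx_p - exact_p), 0.05)
    }
  })

  # agreement with the reference implementation of the same approximation
  w <- suppressWarnings(wilcox.test(c(1, 5, 7), c(2, 2, 9), exact = FALSE))
  got <- rank_sum_compare(c(1, 5, 7), c(2, 2, 9))
  expect_equal(got$p_value, w$p.value)
})
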