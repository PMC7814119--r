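# independent oracles, deliberately implemented with different algorithms
# than the package code they check

# elastic net by accelerated proximal gradient (FISTA), run to high precision
prox_enet_oracle <- function(X, y, alpha, lambda, max_iter = 2e5, tol = 1e-15) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm, "-")
  ym <- mean(y)
  yc <- y - ym
  L <- max(eigen(crossprod(Xc) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  step <- 1 / L
  b <- z <- rep(0, ncol(X))
  t_k <- 1
  for (i in seq_len(max_iter)) {
    grad <- -drop(crossprod(Xc, yc - Xc %*% z)) / n + lambda * (1 - alpha) * z
    u <- z - step * grad
    b_new <- sign(u) * pmax(abs(u) - step * lambda * alpha, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    done <- max(abs(b_new - b)) < tol
    b <- b_new
    t_k <- t_new
    if (done) break
  }
  list(intercept = ym - sum(xm * b), beta = drop(b))
}

# maximum violation of the subgradient optimality conditions of the
# elastic-net objective at (intercept, beta)
kkt_violation <- function(X, y, intercept, beta, alpha, lambda) {
  n <- nrow(X)
  r <- y - intercept - drop(X %*% beta)
  g <- -drop(crossprod(X, r)) / n + lambda * (1 - alpha) * beta
  viol <- ifelse(beta != 0,
                 abs(g + lambda * alpha * sign(beta)),
                 pmax(abs(g) - lambda * alpha, 0))
  max(abs(mean(r)), viol)  # intercept stationarity + coordinate conditions
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
rank_sum_exact_oracle <- function(a, b) {
  values <- c(a, b)
  n1 <- length(a)
  ranks <- rank(values)
  u_of <- function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(values), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# mean per-planted-region Jaccard of called segments vs truth, plus the
# number of called segments not overlapping any planted region
segmentation_recovery <- function(segments, regions) {
  jacc <- function(s1, e1, s2, e2) {
    i <- max(0, min(e1, e2) - max(s1, s2))
    i / ((e1 - s1) + (e2 - s2) - i)
  }
  js <- vapply(seq_len(nrow(regions)), function(i) {
    ov <- segments[segments$chrom == regions$chrom[i] &
                     segments$end > regions$start[i] &
                     segments$start < regions$end[i], ]
    if (nrow(ov) == 0) return(0)
    jacc(min(ov$start), max(ov$end), regions$start[i], regions$end[i])
  }, numeric(1))
  outside <- sum(vapply(seq_len(nrow(segments)), function(k) {
    !any(regions$chrom == segments$chrom[k] &
           regions$end > segments$start[k] &
           regions$start < segments$end[k])
  }, logical(1)))
  list(jaccard = js, n_outside = outside)
}
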