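test_that("spectral factors reproduce the implicit kernel", {
  v <- matrix(c(3, 0, 4, 0, 0, 0))
  f <- spectral_factorize(v)
  expect_equal(f$values, 25)
  expect_equal(abs(drop(f$vectors)), abs(v / 5), ignore_attr = TRUE)

  M <- cbind(c(2, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(spectral_factorize(M)$values, c(4, 1))

  set.seed(31)
  M <- scale(matrix(rnorm(1200), 200, 6), scale = FALSE)
  f <- spectral_factorize(M)
  K <- tcrossprod(M)
  Khat <- f$vectors %*% (f$values * t(f$vectors))
  expect_lt(max(abs(K - Khat)), 1e-8)
  expect_equal(crossprod(f$vectors), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(spectral_factorize(matrix(0, 5, 2)), "all-zero")
})

test_that("trace statistics equal the dense-kernel forms", {
  # orthogonal Z and x give T = 0; Z = x gives the closed-form trace
  x <- c(-1, -1, 1, 1)
  Zo <- matrix(c(1, -1, -1, 1))
  fx <- spectral_factorize(matrix(x))
  expect_equal(wlit_statistic(spectral_factorize(Zo), fx, 4)$T, 0)
  fz <- spectral_factorize(matrix(x))
  expect_equal(wlit_statistic(fz, fx, 4)$T, 4)   # (1/4)(x'x)^2
  expect_equal(ulit_statistic(fz, fx, 4)$T, 1 / 4)

  set.seed(32)
  for (i in 1:3) {
    n <- 100
    Z <- scale(matrix(rnorm(n * 10), n, 10), scale = FALSE)  # r=4 SQ/CP width
    x <- adjust_genotype(rbinom(n, 2, 0.3))
    fz <- spectral_factorize(Z); fx <- spectral_factorize(matrix(x))
    expect_equal(wlit_statistic(fz, fx, n)$T, dense_trace_T(Z, x),
                 tolerance = 1e-8)
    # projection-kernel dense oracle
    Pz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    Px <- tcrossprod(x) / sum(x^2)
    expect_equal(ulit_statistic(fz, fx, n)$T, sum(diag(Px %*% Pz)) / n,
                 tolerance = 1e-8)
  }
})

test_that("weighted tail probabilities match closed forms and Monte Carlo", {
  expect_equal(weighted_chisq_sf(3.841459, 1), 0.05, tolerance = 1e-5)
  expect_equal(weighted_chisq_sf(3, c(0.5, 0.5)), exp(-3), tolerance = 1e-9)
  expect_error(weighted_chisq_sf(1, c(-1, 2)), "non-negative")
  expect_equal(weighted_chisq_sf(0, c(1, 2)), 1)

  set.seed(33)
  w <- c(2, 1, 0.5)
  draws <- 2e6
  s <- 2 * rchisq(draws, 1) + rchisq(draws, 1) + 0.5 * rchisq(draws, 1)
  phat <- mean(s > 7)
  se <- sqrt(phat * (1 - phat) / draws)
  expect_lt(abs(weighted_chisq_sf(7, w) - phat), 3 * se)
})

test_that("weighted tail probability is strictly decreasing in q", {
  w <- c(1.7, 0.9, 0.4, 0.1)
  q <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  p <- vapply(q, weighted_chisq_sf, numeric(1), weights = w)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("saddlepoint and inversion agree where both are reliable", {
  w <- c(1.5, 1, 0.25, 0.1)
  for (q in c(5, 9, 14)) {
    expect_equal(latentgxe:::.saddlepoint_sf(q, w),
                 latentgxe:::.imhof_sf(q, w)$p, tolerance = 0.02)
  }
})

test_that("Cauchy combination identities hold", {
  expect_equal(cauchy_combine(c(0.5, 0.5)), 0.5)
  for (p in c(0.9, 0.5, 0.1, 0.01, 1e-4, 1e-8))
    expect_equal(cauchy_combine(c(p, p)), p, tolerance = 1e-10)
  expect_equal(cauchy_combine(c(0.01, 0.5)), 0.0200, tolerance = 1e-2)
  expect_error(cauchy_combine(numeric(0)), "no p-values")
  expect_error(cauchy_combine(c(0.5, 2)), "lie in")
  # clipping keeps extreme inputs finite
  expect_gt(cauchy_combine(c(0, 0.5)), 0)
  expect_lte(cauchy_combine(c(1, 1)), 1)
})

test_that("single-SNP p-values are uniform under the null", {
  set.seed(34)
  B <- 600
  n <- 150
  pw <- pu <- numeric(B)
  for (b in seq_len(B)) {
    Y <- matrix(rnorm(n * 3), n, 3)
    x <- rbinom(n, 2, 0.3)
    res <- studentize_residuals(residualize(Y, genotype = x))
    r1 <- lit_single_snp(compute_sqcp(res), adjust_genotype(x))
    pw[b] <- r1$p_wlit; pu[b] <- r1$p_ulit
  }
  expect_gt(ks.test(pw, "punif")$p.value, 0.01)
  expect_gt(ks.test(pu, "punif")$p.value, 0.01)
})

test_that("analytic p-values match a permutation oracle on toy data", {
  set.seed(35)
  d <- toy_dataset(n = 60, r = 3, m = 5, tau = 1)
  zx <- toy_Z_x(d)
  r1 <- lit_single_snp(zx$Z, zx$x, permutations = 100000)
  # the analytic p is asymptotic: at n = 60 it tracks the permutation null
  # to within the size of the higher-order moment error (~0.02)
  for (pair in list(c(r1$p_wlit, r1$p_wlit_perm),
                    c(r1$p_ulit, r1$p_ulit_perm))) {
    se <- sqrt(pair[2] * (1 - pair[2]) / 100000)
    expect_lt(abs(pair[1] - pair[2]), 3 * se + 0.02)
  }
})

test_that("duplicated Z columns leave the projection-kernel test unchanged", {
  set.seed(36)
  d <- toy_dataset(n = 200, r = 3, m = 5, tau = 1)
  zx <- toy_Z_x(d)
  r1 <- lit_single_snp(zx$Z, zx$x)
  # duplicating a column leaves the column space (hence d1, the projection
  # kernel, and uLIT) unchanged; the linear kernel legitimately doubles
  # that direction's eigenvalue, so wLIT is not expected to be invariant
  r2 <- lit_single_snp(cbind(zx$Z, zx$Z[, 1]), zx$x)
  expect_equal(r2$d1, r1$d1)
  expect_equal(r1$T_ulit, r2$T_ulit, tolerance = 1e-8)
  expect_equal(r1$p_ulit, r2$p_ulit, tolerance = 1e-6)
  # an exactly collinear (scaled) copy likewise
  r3 <- lit_single_snp(cbind(zx$Z, 2 * zx$Z[, 2]), zx$x)
  expect_equal(r3$d1, r1$d1)
  expect_equal(r1$p_ulit, r3$p_ulit, tolerance = 1e-6)
})

test_that("region test reduces to the single-SNP test and is rank-invariant", {
  set.seed(37)
  d <- toy_dataset(n = 300, r = 3, m = 6, tau = 1)
  zx <- toy_Z_x(d)
  r1 <- lit_single_snp(zx$Z, zx$x)
  rr <- lit_region(zx$Z, matrix(zx$x))
  expect_equal(rr$p_wlit, r1$p_wlit, tolerance = 1e-10)
  expect_equal(rr$p_ulit, r1$p_ulit, tolerance = 1e-10)
  expect_warning(r2 <- lit_region(zx$Z, cbind(zx$x, zx$x)), "collinear")
  expect_equal(r2$p_wlit, r1$p_wlit, tolerance = 1e-8)
  expect_equal(r2$d2, 1L)
})

test_that("region test keeps uniform p-values under the null", {
  set.seed(38)
  B <- 250
  n <- 200
  pu <- numeric(B)
  for (b in seq_len(B)) {
    Y <- matrix(rnorm(n * 2), n, 2)
    X <- sapply(runif(5, 0.2, 0.4), function(p) rbinom(n, 2, p))
    res <- studentize_residuals(residualize(Y, covariates = X))
    Xa <- apply(X, 2, function(g) adjust_genotype(g))
    pu[b] <- lit_region(compute_sqcp(res), Xa)$p_ulit
  }
  expect_gt(ks.test(pu, "punif")$p.value, 0.01)
})

test_that("statistics are invariant to joint sample permutation", {
  set.seed(39)
  d <- toy_dataset(n = 120, r = 3, m = 4, tau = 1)
  zx <- toy_Z_x(d)
  perm <- sample(nrow(zx$Z))
  r1 <- lit_single_snp(zx$Z, zx$x)
  r2 <- lit_single_snp(zx$Z[perm, ], zx$x[perm])
  expect_equal(r1$T_wlit, r2$T_wlit, tolerance = 1e-10)
  expect_equal(r1$p_alit, r2$p_alit, tolerance = 1e-10)
  # uLIT is invariant to orthogonal rotation of the Z column basis
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  r3 <- lit_single_snp(zx$Z %*% Q, zx$x)
  expect_equal(r1$T_ulit, r3$T_ulit, tolerance = 1e-8)
  expect_equal(r1$p_ulit, r3$p_ulit, tolerance = 1e-6)
})

test_that("double-centering the kernel coincides with centered features", {
  # HSIC's H K H centering equals building the kernel from column-centered
  # features, for the linear kernel
  set.seed(40)
  n <- 50
  Zr <- matrix(rnorm(n * 4), n, 4) + 2      # deliberately uncentered
  Zc <- scale(Zr, scale = FALSE)
  H <- diag(n) - 1 / n
  K_centered_features <- tcrossprod(Zc)
  K_double_centered <- H %*% tcrossprod(Zr) %*% H
  expect_equal(K_centered_features, K_double_centered, tolerance = 1e-8)
})
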