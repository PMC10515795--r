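test_that("genomic inflation factor hits its reference points", {
  expect_warning(l1 <- genomic_inflation(rep(0.5, 50)), "fewer than 100")
  expect_equal(l1, 1)
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  set.seed(61)
  p2 <- pchisq(2 * rchisq(20000, 1), df = 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), 2, tolerance = 0.05)
  pu <- runif(1e5)
  expect_equal(genomic_inflation(pu), 1, tolerance = 0.02)
})

test_that("genomic-control adjustment is the chi-squared deflation map", {
  p <- c(0.9, 0.5, 0.05, 1e-6)
  expect_identical(gc_adjust(p, 1), p)
  expect_identical(gc_adjust(p, 0.8), p)    # deflation never inflates
  expect_equal(gc_adjust(0.05, 2), 0.1658, tolerance = 1e-3)
  set.seed(62)
  pr <- sort(runif(50))
  expect_identical(order(gc_adjust(pr, 1.37)), order(pr))
  expect_true(all(gc_adjust(pr, 1.37) >= pr))
})

test_that("inflation report summarizes both kernels and MAF bins", {
  set.seed(63)
  p1 <- runif(500); p2 <- runif(500)
  maf <- runif(500, 0.05, 0.5)
  f <- tempfile(fileext = ".json")
  rep_ <- inflation_report(p1, p2, maf = maf, json_path = f)
  expect_named(rep_$lambda_gc, c("wlit", "ulit"))
  expect_true(all(rep_$lambda_gc > 0))
  if (requireNamespace("jsonlite", quietly = TRUE))
    expect_true(file.exists(f))
})

test_that("cross-trait additive test reduces to the score test for r = 1", {
  set.seed(64)
  n <- 400
  x <- rbinom(n, 2, 0.3)
  y <- 0.1 * x + rnorm(n)
  xa <- adjust_genotype(x)
  res <- residualize(matrix(y))
  p <- additive_cross_trait_test(res, xa)
  rho <- cor(res$residuals[, 1], xa)
  # the score test with the permutation-mean degrees-of-freedom factor
  oracle <- pchisq((n - 1) * rho^2, 1, lower.tail = FALSE)
  expect_equal(as.numeric(p), oracle, tolerance = 1e-10)
  # and the plain n rho^2 form to within its O(1/n) difference
  expect_equal(as.numeric(p), pchisq(n * rho^2, 1, lower.tail = FALSE),
               tolerance = 1e-2)
})

test_that("cross-trait additive test is calibrated and powered", {
  set.seed(65)
  B <- 300; n <- 300
  p0 <- numeric(B)
  for (b in seq_len(B)) {
    Y <- matrix(rnorm(n * 3), n, 3)
    x <- adjust_genotype(rbinom(n, 2, 0.3))
    p0[b] <- additive_cross_trait_test(residualize(Y), x)
  }
  expect_gt(ks.test(p0, "punif")$p.value, 0.01)
  # strong additive signal at n = 1e4 crosses genome-wide significance
  n <- 1e4
  x <- rbinom(n, 2, 0.3)
  Y <- cbind(0.3 * x + rnorm(n), rnorm(n))
  p1 <- additive_cross_trait_test(residualize(Y), adjust_genotype(x))
  expect_lt(as.numeric(p1), 5e-8)
})

test_that("LD adjustment rescues an additive-confound false positive", {
  set.seed(66)
  n <- 8000
  causal <- rbinom(n, 2, 0.3)
  flip <- runif(n) < 0.3                     # strong LD with the lead SNP
  lead <- ifelse(flip, rbinom(n, 2, 0.3), causal)
  Y <- cbind(1.0 * causal + rnorm(n), 1.0 * causal + rnorm(n))
  Ys <- standardize_traits(Y)
  plain <- lit_single_snp(
    compute_sqcp(studentize_residuals(residualize(Ys, genotype = lead))),
    adjust_genotype(lead))
  adj <- ld_adjust_retest(Ys, lead, neighbors = cbind(causal), alpha = 1e-4)
  expect_lt(plain$p_alit, 1e-4)              # confound masquerades as GxE
  expect_equal(adj$n_regressed, 1L)
  expect_gt(adj$p_alit, 1e-4)                # rescued after adjustment
  # with no neighbors the unadjusted result is returned
  no_nb <- ld_adjust_retest(Ys, lead)
  expect_equal(no_nb$p_alit, plain$p_alit, tolerance = 1e-10)
  expect_equal(no_nb$n_regressed, 0L)
})

test_that("a true latent interaction survives the LD adjustment", {
  set.seed(67)
  n <- 8000
  lead <- rbinom(n, 2, 0.3)
  nb <- ifelse(runif(n) < 0.2, rbinom(n, 2, 0.3), lead)
  M <- rnorm(n)
  Y <- cbind(0.1 * nb + 0.25 * M + 0.22 * M * lead + rnorm(n),
             0.1 * nb + 0.25 * M + 0.22 * M * lead + rnorm(n))
  adj <- ld_adjust_retest(standardize_traits(Y), lead,
                          neighbors = cbind(nb), alpha = 1e-3)
  expect_lt(adj$p_alit, 1e-6)
})

test_that("dominance adjustment absorbs genotype-level mean functions", {
  set.seed(68)
  n <- 4000
  B <- 30
  p_plain <- p_dom <- numeric(B)
  for (b in seq_len(B)) {
    x <- rbinom(n, 2, 0.3)
    Y <- cbind(1.2 * (x == 2) + rnorm(n), 1.2 * (x == 2) + rnorm(n))
    Ys <- standardize_traits(Y)
    p_plain[b] <- lit_single_snp(
      compute_sqcp(studentize_residuals(residualize(Ys, genotype = x))),
      adjust_genotype(x))$p_alit
    p_dom[b] <- dominance_retest(Ys, x)$p_alit
  }
  # additive-only adjustment leaves spurious variance signal; the 2-df
  # model removes it, restoring type-I control (slightly conservative)
  expect_gt(mean(p_plain < 0.05), 0.6)
  binom_hi <- 0.05 + 3 * sqrt(0.05 * 0.95 / B)
  expect_lte(mean(p_dom < 0.05), binom_hi)
})

test_that("dominance and additive adjustments coincide for linear traits", {
  x <- rep(c(0, 1, 2), each = 20)
  y <- matrix(1.3 * x + 0.5)
  r_add <- residualize(y, genotype = x)
  r_dom <- residualize(y, genotype = x, dominance = TRUE)
  expect_lt(max(abs(r_add$residuals)), 1e-10)
  expect_lt(max(abs(r_dom$residuals)), 1e-10)
  expect_error(dominance_retest(matrix(rnorm(10)), rep(1, 10)), "2 observed")
})

test_that("a true interaction survives the dominance adjustment", {
  set.seed(69)
  n <- 8000
  x <- rbinom(n, 2, 0.3)
  M <- rnorm(n)
  Y <- cbind(0.25 * M + 0.2 * M * x + rnorm(n),
             0.25 * M + 0.2 * M * x + rnorm(n))
  p <- dominance_retest(standardize_traits(Y), x)$p_alit
  expect_lt(p, 1e-6)
})

test_that("IAF standardization matches the no-structure closed form", {
  set.seed(70)
  x <- rbinom(500, 2, 0.3)
  ph <- mean(x) / 2
  expect_equal(iaf_standardize(x),
               (x - 2 * ph) / sqrt(2 * ph * (1 - ph)), ignore_attr = TRUE)
  expect_error(iaf_standardize(rep(0, 100)), "monomorphic")
})

test_that("IAF standardization equalizes variance across subpopulations", {
  set.seed(71)
  n <- 4000
  pop <- rep(0:1, each = n / 2)
  p <- ifelse(pop == 0, 0.1, 0.45)
  x <- rbinom(n, 2, p)
  xs <- iaf_standardize(x, structure_axes = cbind(pop))
  v0 <- var(xs[pop == 0]); v1 <- var(xs[pop == 1])
  expect_equal(v0, 1, tolerance = 0.1)
  expect_equal(v1, 1, tolerance = 0.1)
  # plain standardization leaves unequal variances
  xp <- iaf_standardize(x)
  expect_gt(abs(var(xp[pop == 0]) - var(xp[pop == 1])), 0.3)
})
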