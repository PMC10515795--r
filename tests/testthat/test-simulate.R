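test_that("configuration validates its variance budget and tau", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(baseline_corr = 0.1), "at least")
  expect_error(sim_config(tau = 1.2), "tau")
  expect_error(sim_config(pve_risk_snp = 0.9), "budget")
  cfg <- sim_config(r = 5, tau = 0.8)
  expect_equal(cfg$n_interacting, 4L)
  expect_equal(sim_config(baseline_corr = 0.5)$pve_additive_background, 0.35)
})

test_that("component standardization is exact and idempotent", {
  expect_equal(scale_component(c(0, 2)), c(-1, 1) / sd(c(0, 2)) * 1,
               tolerance = 1e-12)
  set.seed(81)
  x <- rexp(100)
  f <- scale_component(x)
  expect_equal(mean(f), 0, tolerance = 1e-14)
  expect_equal(sd(f), 1, tolerance = 1e-14)
  expect_equal(scale_component(f), f, tolerance = 1e-12)
  expect_error(scale_component(rep(3, 10)), "constant")
})

test_that("genotypes follow the configured allele frequencies", {
  set.seed(82)
  cfg <- sim_config(n = 1e5, r = 5, m = 20)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$X %in% 0:2))
  expect_equal(g$maf[1], 0.25)
  expect_true(all(g$maf[-1] >= 0.1 & g$maf[-1] <= 0.4))
  # SNP 1 empirical frequency within 3 binomial SEs of 0.25
  se <- sqrt(0.25 * 0.75 / (2 * cfg$n))
  expect_lt(abs(mean(g$X[, 1]) / 2 - 0.25), 3 * se)
  # binomial mean check for a background SNP
  expect_equal(mean(g$X[, 5]), 2 * g$maf[5], tolerance = 0.02)
})

test_that("traits carry the configured variance budget and correlation", {
  set.seed(83)
  cfg <- sim_config(n = 1e5, r = 5, m = 50, baseline_corr = 0.5, tau = 0)
  d <- simulate_lit_data(cfg)
  # total non-intercept variance ~ 1
  expect_equal(unname(apply(d$traits, 2, var)), rep(1, 5), tolerance = 0.03)
  # baseline correlation after removing the risk-SNP, interacting-env and
  # GxE components (they are excluded from the baseline by definition)
  Yb <- d$traits -
    d$components[, "env"] %*% t(sqrt(d$truth$pve_env)) -
    d$components[, "risk"] %*% t(rep(sqrt(cfg$pve_risk_snp), 5))
  cc <- cor(Yb)
  expect_equal(mean(cc[upper.tri(cc)]), 0.5, tolerance = 0.02)
})

test_that("realized component PVEs match their budgets", {
  set.seed(84)
  cfg <- sim_config(n = 15e4, r = 4, m = 50, baseline_corr = 0.25, tau = 1)
  d <- simulate_lit_data(cfg)
  # the components are deliberately correlated (the GxE product shares the
  # environment and the genotype), so recover coefficients jointly
  for (k in 1:4) {
    co <- coef(lm(d$traits[, k] ~ d$components))[-1]
    expected <- c(sqrt(cfg$pve_risk_snp), sqrt(d$truth$pve_env[k]),
                  d$truth$gamma_sign[k] * sqrt(d$truth$pve_gxe[k]),
                  sqrt(cfg$pve_additive_background),
                  sqrt(cfg$pve_env_noninteracting))
    expect_equal(unname(co), expected, tolerance = 0.05)
    # squared coefficients are the realized variance fractions
    expect_equal(unname(co^2), expected^2, tolerance = 0.1)
  }
})

test_that("pleiotropy modes set the interaction signs", {
  set.seed(85)
  cfg <- function(mode) sim_config(n = 500, r = 6, m = 5, tau = 1,
                                   pleiotropy = mode)
  d_pos <- simulate_lit_data(cfg("positive"))
  expect_true(all(d_pos$truth$gamma_sign == 1))
  d_opp <- simulate_lit_data(cfg("positive_opposed"))
  expect_true(all(d_opp$truth$gamma_sign == -1))
  d_mix <- simulate_lit_data(cfg("mixed"))
  expect_true(all(d_mix$truth$gamma_sign %in% c(-1, 1)))
  # tau = 0.5: only the first half interact
  d_half <- simulate_lit_data(sim_config(n = 500, r = 6, m = 5, tau = 0.5))
  expect_equal(d_half$truth$gamma_sign, c(rep(1, 3), rep(0, 3)))
  expect_equal(d_half$truth$pve_gxe[4:6], rep(0, 3))
})

test_that("seeded runs are bit-reproducible", {
  cfg <- sim_config(n = 300, r = 3, m = 10)
  set.seed(86); d1 <- simulate_lit_data(cfg)
  set.seed(86); d2 <- simulate_lit_data(cfg)
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$genotypes, d2$genotypes)
})

test_that("null batches have the configured error shapes", {
  set.seed(87)
  e_chi <- latentgxe:::.sim_errors(5e4, 2, "chisq5")
  skew <- mean(e_chi[, 1]^3)
  expect_equal(skew, sqrt(8 / 5), tolerance = 0.1)
  expect_equal(sd(e_chi[, 1]), 1, tolerance = 0.02)
  e_t <- latentgxe:::.sim_errors(5e4, 1, "t3")
  e_n <- latentgxe:::.sim_errors(5e4, 1, "normal")
  # heavy tails: extreme quantile ratio well above the normal's
  expect_gt(quantile(abs(e_t), 0.999) / quantile(abs(e_n), 0.999), 1.5)
  # streaming interface with no interaction
  out <- simulate_null_batch(sim_config(n = 200, r = 2, m = 5), 2, 5,
                             FUN = function(d) d$truth$pve_gxe)
  expect_length(out, 2)
  expect_true(all(unlist(out) == 0))
})

test_that("power collapses to alpha under the null and to 1 at alpha = 1", {
  set.seed(88)
  cfg0 <- sim_config(n = 1500, r = 3, m = 10, tau = 0)
  res0 <- power_experiment(cfg0, n_reps = 60, alpha = 0.05)
  for (m in c("power_alit", "power_wlit", "power_ulit"))
    expect_lte(res0[[m]], 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  res1 <- power_experiment(cfg0, n_reps = 10, alpha = 1)
  expect_equal(res1$power_alit, 1)
  expect_equal(res1$power_wlit, 1)
  expect_equal(res1$power_ulit, 1)
})

test_that("type-I driver controls the error rate at moderate scale", {
  set.seed(89)
  cfg <- sim_config(n = 2000, r = 3, m = 100)
  t1 <- type1_experiment(cfg, n_datasets = 2, snps_per_dataset = 400,
                         alpha = 0.01, chunk_size = 150)
  expect_equal(t1$n_tests, 800)
  for (m in c("p_wlit", "p_ulit", "p_alit")) {
    rate <- t1$rates[[m]]
    expect_lt(abs(rate - 0.01), 4 * sqrt(0.01 * 0.99 / 800) + 0.005)
  }
  # two-pass RNG replay leaves the stream deterministic
  set.seed(89)
  cfg2 <- sim_config(n = 2000, r = 3, m = 100)
  t2 <- type1_experiment(cfg2, n_datasets = 2, snps_per_dataset = 400,
                         alpha = 0.01, chunk_size = 150)
  expect_identical(t1$pvalues, t2$pvalues)
})
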