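## Polygenic gene-by-environment simulator: binomial genotypes, two latent
## environments (one interacting), shared polygenic background controlling
## the baseline trait correlation, and per-trait variance budgets.

#' Simulation configuration
#'
#' Defines the generative model for the multi-trait latent-interaction
#' study design: `n` individuals, `r` traits, `m` biallelic SNPs of which
#' SNP 1 carries the interaction (minor allele frequency fixed at
#' `maf_interacting` to remove MAF-driven power variation) and SNPs
#' 2..m form the additive polygenic background with MAFs drawn from
#' `maf_range`. Trait variance budgets: additive risk SNP
#' `pve_risk_snp` (0.2%), interacting environment drawn per trait from
#' `pve_interacting_env_range` (0.5-2%), GxE drawn per trait from
#' `pve_gxe_range` (0.1-0.15%), non-interacting shared environment
#' `pve_env_noninteracting` (15%), shared polygenic background
#' `baseline_corr - pve_env_noninteracting` (10/35/60% for baseline
#' correlations 0.25/0.50/0.75), remainder noise. `tau` is the proportion
#' of traits carrying the interaction; `pleiotropy` sets the sign pattern
#' of the interaction effects relative to the (positive) environment
#' effect.
#'
#' @param n,r,m sample, trait, and SNP counts.
#' @param maf_interacting MAF of the interacting SNP.
#' @param maf_range MAF range of the background SNPs.
#' @param baseline_corr baseline inter-trait correlation from shared
#'   background genetics plus shared environment (0.25, 0.50 or 0.75 in
#'   the reference design).
#' @param pve_env_noninteracting variance fraction of the shared
#'   non-interacting environment.
#' @param pve_risk_snp variance fraction of the risk SNP's additive
#'   effect.
#' @param pve_interacting_env_range,pve_gxe_range per-trait uniform draw
#'   ranges for the interacting environment and GxE variance fractions.
#' @param tau proportion of traits with the shared interaction
#'   (`round(tau * r)` traits, the first ones).
#' @param pleiotropy `"positive"` (all interaction effects share the
#'   environment's sign), `"mixed"` (independent random signs),
#'   `"positive_opposed"` (all opposite the environment), or
#'   `"mixed_opposed"` (random signs, opposed parameterization).
#' @param error_dist noise distribution: `"normal"`, `"chisq5"`
#'   (skewed), or `"t3"` (heavy-tailed); non-normal draws are centered and
#'   scaled to unit variance.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n = 300000L, r = 5L, m = 100L,
                       maf_interacting = 0.25, maf_range = c(0.1, 0.4),
                       baseline_corr = 0.25,
                       pve_env_noninteracting = 0.15,
                       pve_risk_snp = 0.002,
                       pve_interacting_env_range = c(0.005, 0.02),
                       pve_gxe_range = c(0.001, 0.0015),
                       tau = 0.8,
                       pleiotropy = c("positive", "mixed",
                                      "positive_opposed", "mixed_opposed"),
                       error_dist = c("normal", "chisq5", "t3")) {
  pleiotropy <- match.arg(pleiotropy)
  error_dist <- match.arg(error_dist)
  pve_bg <- baseline_corr - pve_env_noninteracting
  if (pve_bg < 0)
    stop("baseline_corr must be at least pve_env_noninteracting")
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  budget <- pve_risk_snp + max(pve_interacting_env_range) +
    max(pve_gxe_range) + pve_bg + pve_env_noninteracting
  if (budget > 1) stop("variance budget exceeds 1 (total ", round(budget, 3), ")")
  structure(list(n = as.integer(n), r = as.integer(r), m = as.integer(m),
                 maf_interacting = maf_interacting, maf_range = maf_range,
                 baseline_corr = baseline_corr,
                 pve_env_noninteracting = pve_env_noninteracting,
                 pve_additive_background = pve_bg,
                 pve_risk_snp = pve_risk_snp,
                 pve_interacting_env_range = pve_interacting_env_range,
                 pve_gxe_range = pve_gxe_range,
                 tau = tau, n_interacting = as.integer(round(tau * r)),
                 pleiotropy = pleiotropy, error_dist = error_dist),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Latent-interaction simulation design\n")
  cat("  n =", x$n, ", traits r =", x$r, ", SNPs m =", x$m, "\n")
  cat("  baseline correlation", x$baseline_corr,
      "(background PVE", x$pve_additive_background,
      "+ shared env", x$pve_env_noninteracting, ")\n")
  cat("  interacting traits:", x$n_interacting, "of", x$r,
      "(tau =", x$tau, "),", x$pleiotropy, "pleiotropy,",
      x$error_dist, "errors\n")
  invisible(x)
}

#' Standardize a simulation component
#'
#' `f(x) = (x - mean(x)) / sd(x)` with the sample (n-1) standard
#' deviation; every model component is passed through this before being
#' scaled to its variance budget.
#'
#' @param x non-constant numeric vector.
#' @return vector with mean 0, sd 1.
#' @export
scale_component <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant component")
  (x - mean(x)) / s
}

#' Simulate genotypes
#'
#' SNP 1 (the interacting SNP) has MAF parameter `maf_interacting`
#' exactly; SNPs 2..m have MAFs drawn uniformly from `maf_range`. Allele
#' counts are Binomial(2, maf).
#'
#' @param config a [sim_config()].
#' @return list with `X` (n x m integer matrix of allele counts) and
#'   `maf` (the MAF parameters).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  maf <- c(config$maf_interacting,
           if (config$m > 1L) runif(config$m - 1L, config$maf_range[1L],
                                    config$maf_range[2L]))
  list(X = cpp_binom2_matrix(config$n, maf), maf = maf)
}

## Standardized noise draws for each error family (unit-scaled columns).
.sim_errors <- function(n, r, dist) {
  code <- match(dist, c("normal", "chisq5", "t3")) - 1L
  cpp_noise_matrix(n, r, code, rep.int(1, r))
}

## Interaction sign pattern per trait (length = number of interacting traits).
.gxe_signs <- function(k, pleiotropy) {
  if (k == 0L) return(numeric(0))
  switch(pleiotropy,
         positive = rep.int(1, k),
         mixed = sample(c(-1, 1), k, replace = TRUE),
         positive_opposed = rep.int(-1, k),
         mixed_opposed = sample(c(-1, 1), k, replace = TRUE))
}

## Core trait builder shared by the stored-genotype and streaming paths.
## x1: interacting SNP dosages; bg_score: raw polygenic score (or NULL when
## pve_bg = 0). Returns traits plus the truth/actualized-parameter record.
.build_traits <- function(x1, bg_score, config) {
  n <- config$n; r <- config$r
  k_int <- config$n_interacting
  M <- rnorm(n)
  W <- rnorm(n)
  c_risk <- scale_component(x1)
  c_env <- scale_component(M)
  c_gxe <- scale_component(M * x1)     # product formed before standardization
  c_w <- scale_component(W)
  if (config$pve_additive_background > 0 && is.null(bg_score))
    stop("background PVE > 0 requires a polygenic score (m > 1)")
  c_bg <- if (config$pve_additive_background > 0) scale_component(bg_score)
          else numeric(n)
  pve_env <- runif(r, config$pve_interacting_env_range[1L],
                   config$pve_interacting_env_range[2L])
  pve_gxe <- numeric(r)
  gamma_sign <- numeric(r)
  if (k_int > 0L) {
    pve_gxe[seq_len(k_int)] <- runif(k_int, config$pve_gxe_range[1L],
                                     config$pve_gxe_range[2L])
    gamma_sign[seq_len(k_int)] <- .gxe_signs(k_int, config$pleiotropy)
  }
  pve_noise <- 1 - (config$pve_risk_snp + pve_env + pve_gxe +
                    config$pve_additive_background +
                    config$pve_env_noninteracting)
  if (any(pve_noise < 0)) stop("variance budget exceeds 1 for some trait")
  alpha <- rnorm(r, 0, 5)
  comp <- cbind(risk = c_risk, env = c_env, gxe = c_gxe, bg = c_bg, w = c_w)
  coef <- cbind(risk = rep.int(sqrt(config$pve_risk_snp), r),
                env = sqrt(pve_env),
                gxe = gamma_sign * sqrt(pve_gxe),
                bg = rep.int(sqrt(config$pve_additive_background), r),
                w = rep.int(sqrt(config$pve_env_noninteracting), r))
  code <- match(config$error_dist, c("normal", "chisq5", "t3")) - 1L
  Y <- comp %*% t(coef) +
    cpp_noise_matrix(n, r, code, sqrt(pve_noise)) +
    rep(alpha, each = n)
  colnames(Y) <- paste0("trait", seq_len(r))
  list(traits = Y,
       truth = list(alpha = alpha, pve_env = pve_env, pve_gxe = pve_gxe,
                    pve_noise = pve_noise, gamma_sign = gamma_sign,
                    interacting = seq_len(k_int), M = M, W = W),
       components = comp)
}

#' Simulate traits from a genotype matrix
#'
#' Builds each trait as the sum of standardized components scaled to
#' their variance budgets: the risk SNP's additive effect, the
#' interacting environment, the GxE product (formed before
#' standardization), the shared polygenic background score (one
#' realization shared by all traits), the shared non-interacting
#' environment, and noise, plus a Normal(0, 5^2) intercept. Exactly
#' `round(tau * r)` traits (the first ones) receive a non-zero
#' interaction, with signs set by the pleiotropy mode.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param config the [sim_config()].
#' @return object of class `"sim_dataset"`: list with `traits` (n x r),
#'   `genotypes`, `maf`, `config`, `truth` (realized draws sufficient to
#'   recompute every component's PVE), and `components` (the standardized
#'   shared components).
#' @export
simulate_traits <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  X <- genotypes$X
  beta_bg <- if (config$m > 1L) rnorm(config$m - 1L, 0, 0.01) else numeric(0)
  bg <- if (config$m > 1L && config$pve_additive_background > 0)
    drop(X[, -1L, drop = FALSE] %*% beta_bg) else NULL
  built <- .build_traits(as.numeric(X[, 1L]), bg, config)
  built$truth$beta_bg <- beta_bg
  structure(list(traits = built$traits, genotypes = X, maf = genotypes$maf,
                 config = config, truth = built$truth,
                 components = built$components),
            class = "sim_dataset")
}

#' Simulate a complete dataset
#'
#' [simulate_genotypes()] followed by [simulate_traits()].
#'
#' @param config a [sim_config()].
#' @return a `"sim_dataset"`.
#' @export
simulate_lit_data <- function(config) {
  simulate_traits(simulate_genotypes(config), config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated latent-interaction dataset: n =", nrow(x$traits),
      ", r =", ncol(x$traits), ", m =", ncol(x$genotypes), "\n")
  print(x$config)
  invisible(x)
}

#' Stream null datasets (no GxE interaction)
#'
#' Generates datasets under the null design: the full polygenic model
#' with `tau = 0` so no trait carries an interaction, with the configured
#' error distribution (skewed chi-squared-5 or heavy-tailed t-3 noise are
#' centered and scaled to unit variance). Intended for type-I-error
#' studies at moderate sizes; the scalable chunked driver is
#' [type1_experiment()].
#'
#' @param config a [sim_config()]; `tau` is forced to 0 and `m` to
#'   `snps_per_dataset`.
#' @param n_datasets number of datasets.
#' @param snps_per_dataset SNPs per dataset.
#' @param FUN optional function applied to each `"sim_dataset"` as it is
#'   generated (streaming); its results are collected in a list. When
#'   `NULL` the datasets themselves are returned.
#' @return list of length `n_datasets`.
#' @export
simulate_null_batch <- function(config, n_datasets = 50L,
                                snps_per_dataset = 10000L, FUN = NULL) {
  cfg <- config
  cfg$tau <- 0; cfg$n_interacting <- 0L
  cfg$m <- as.integer(snps_per_dataset)
  lapply(seq_len(n_datasets), function(i) {
    d <- simulate_lit_data(cfg)
    if (is.null(FUN)) d else FUN(d)
  })
}
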