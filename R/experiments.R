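## Power and type-I-error study drivers. The power path tests only the
## interacting SNP per replicate; the type-I path scans every simulated SNP
## in chunks with two-pass RNG replay so genotypes are never stored whole.

## Convert one row of cpp scan output into the five test p-values.
.lit_row_pvalues <- function(lam, w, xx, n, d2 = 1L) {
  T_w <- sum(w^2) / n
  p_w <- weighted_chisq_sf(T_w, lam * xx / (n * (n - 1)))
  T_u <- sum(w^2 / (lam * xx)) / n
  p_u <- min(1, max(1e-300, pchisq(n * (n - 1) * T_u,
                                   df = length(lam) * d2,
                                   lower.tail = FALSE)))
  c(T_wlit = T_w, p_wlit = p_w, T_ulit = T_u, p_ulit = p_u,
    p_alit = cauchy_combine(c(p_w, p_u)))
}

## Marginal minimum-p Bonferroni rejection from kernel cross products.
## C: centered Z'Z; v: Z'x; cols: column subset to use.
.marginal_from_cross <- function(C, v, xx, n, cols, alpha) {
  Cd <- diag(C)[cols]
  ok <- Cd > 0
  rho <- rep.int(0, length(cols))
  rho[ok] <- v[cols][ok] / sqrt(Cd[ok] * xx)
  rho <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  p <- 2 * pnorm(-abs(rho) * sqrt(n))
  p[!ok] <- 1
  Cs <- C[cols, cols, drop = FALSE]
  d <- sqrt(diag(Cs))
  ev <- eigen(Cs / tcrossprod(d), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  K <- which(cumsum(ev) / sum(ev) >= 0.95 - 1e-12)[1L]
  list(min_p = min(p), K = K, reject = min(p) < alpha / K)
}

## One fast power replicate: simulate the design, test SNP 1, return the
## LIT p-values and marginal rejections.
.power_replicate <- function(config, alpha = 5e-8, rank_tol = 1e-10) {
  n <- config$n
  r <- config$r
  x1 <- rbinom(n, 2L, config$maf_interacting)
  bg <- NULL
  if (config$pve_additive_background > 0) {
    if (config$m < 2L) stop("background PVE requires m > 1")
    p_bg <- runif(config$m - 1L, config$maf_range[1L], config$maf_range[2L])
    beta <- rnorm(config$m - 1L, 0, 0.01)
    bg <- cpp_bg_score(n, p_bg, beta)
  }
  built <- .build_traits(as.numeric(x1), bg, config)
  Y <- built$traits
  for (k in seq_len(r)) Y[, k] <- scale_component(Y[, k])
  xc <- x1 - mean(x1)
  xx <- sum(xc^2)
  ahat <- drop(crossprod(Y, xc)) / xx
  E0 <- Y - tcrossprod(xc, ahat)
  h <- 1 / n + xc^2 / xx
  E0 <- E0 / sqrt(1 - h)
  E0 <- sweep(E0, 2L, colMeans(E0))
  cs <- cpp_sqcp_cross(E0, xc, include_cp = TRUE)
  es <- eigen(cs$C, symmetric = TRUE)
  keep <- es$values > rank_tol * es$values[1L] & es$values > 0
  lam <- es$values[keep]
  w <- drop(crossprod(es$vectors[, keep, drop = FALSE], cs$v))
  lit <- .lit_row_pvalues(lam, w, xx, n)
  d <- ncol(cs$C)
  m_sqcp <- .marginal_from_cross(cs$C, cs$v, xx, n, seq_len(d), alpha)
  m_sq <- .marginal_from_cross(cs$C, cs$v, xx, n, seq_len(r), alpha)
  c(p_alit = unname(lit["p_alit"]), p_wlit = unname(lit["p_wlit"]),
    p_ulit = unname(lit["p_ulit"]),
    rej_marg_sqcp = as.numeric(m_sqcp$reject),
    rej_marg_sq = as.numeric(m_sq$reject))
}

#' Empirical power over simulation replicates
#'
#' For each configuration, repeatedly simulates the design, runs the
#' latent-interaction tests (aLIT, wLIT, uLIT) and the marginal
#' minimum-p procedures (SQ/CP and SQ-only) at the interacting SNP, and
#' reports the fraction of replicates below `alpha` with binomial
#' standard errors. The m - 1 background SNPs enter through the shared
#' polygenic score; testing is performed at SNP 1 only.
#'
#' @param configs a [sim_config()] or list of them (the grid cells).
#' @param n_reps replicates per cell.
#' @param alpha significance threshold (genome-wide 5e-8 by default).
#' @param verbose print per-cell progress.
#' @return data frame with one row per cell: design labels, powers
#'   (`power_alit`, `power_wlit`, `power_ulit`, `power_marg_sqcp`,
#'   `power_marg_sq`) and standard errors.
#' @export
power_experiment <- function(configs, n_reps = 500L, alpha = 5e-8,
                             verbose = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    res <- vapply(seq_len(n_reps), function(b) .power_replicate(cfg, alpha),
                  numeric(5))
    rej <- rbind(res["p_alit", ] < alpha, res["p_wlit", ] < alpha,
                 res["p_ulit", ] < alpha, res["rej_marg_sqcp", ] > 0,
                 res["rej_marg_sq", ] > 0)
    pow <- rowMeans(rej)
    se <- sqrt(pow * (1 - pow) / n_reps)
    out <- data.frame(r = cfg$r, baseline_corr = cfg$baseline_corr,
                      tau = cfg$tau, pleiotropy = cfg$pleiotropy,
                      n = cfg$n, n_reps = n_reps, alpha = alpha,
                      power_alit = pow[1L], power_wlit = pow[2L],
                      power_ulit = pow[3L], power_marg_sqcp = pow[4L],
                      power_marg_sq = pow[5L],
                      se_alit = se[1L], se_wlit = se[2L], se_ulit = se[3L],
                      se_marg_sqcp = se[4L], se_marg_sq = se[5L])
    if (verbose)
      message(sprintf("cell %d/%d: aLIT %.3f, SQ/CP %.3f", i,
                      length(configs), pow[1L], pow[4L]))
    out
  })
  do.call(rbind, rows)
}

## Compute LIT p-values for every SNP of a cpp_lit_scan result.
.scan_pvalues <- function(sc) {
  m <- nrow(sc$lambda)
  n <- sc$n
  out <- matrix(NA_real_, m, 5L,
                dimnames = list(NULL, c("T_wlit", "p_wlit", "T_ulit",
                                        "p_ulit", "p_alit")))
  for (s in seq_len(m)) {
    d1 <- sc$d1[s]
    if (d1 <= 0L) next
    idx <- seq_len(d1)
    out[s, ] <- .lit_row_pvalues(sc$lambda[s, idx], sc$w[s, idx],
                                 sc$xx[s], n)
  }
  out
}

#' Type-I-error study under the null polygenic design
#'
#' Simulates datasets with no GxE interaction (the full polygenic model
#' with `tau = 0`; every simulated SNP contributes a small additive
#' effect through the background score and none interacts) and scans all
#' SNPs with the latent-interaction tests. Genotypes are generated in
#' chunks twice — once to accumulate the polygenic score, once (replaying
#' the recorded RNG states) to test — so memory stays at
#' O(n x chunk_size). Error distributions cycle through `error_dists`
#' across datasets.
#'
#' @param config a [sim_config()] giving n, r, variance budgets.
#' @param n_datasets number of independent datasets.
#' @param snps_per_dataset SNPs simulated and tested per dataset.
#' @param alpha nominal level at which rejections are counted.
#' @param error_dists error distributions cycled across datasets.
#' @param chunk_size SNPs per genotype chunk.
#' @return object of class `"type1_result"`: list with per-method
#'   empirical rates, rejection counts, total test count, the exact 95%
#'   binomial confidence interval for the count under the nominal level,
#'   and the pooled p-values.
#' @export
type1_experiment <- function(config, n_datasets = 10L,
                             snps_per_dataset = 10000L, alpha = 1e-3,
                             error_dists = c("normal", "chisq5", "t3"),
                             chunk_size = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  pv <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    cfg <- config
    cfg$tau <- 0; cfg$n_interacting <- 0L
    cfg$m <- as.integer(snps_per_dataset)
    cfg$error_dist <- error_dists[(d - 1L) %% length(error_dists) + 1L]
    m <- cfg$m
    maf <- c(cfg$maf_interacting,
             runif(m - 1L, cfg$maf_range[1L], cfg$maf_range[2L]))
    beta_bg <- rnorm(m - 1L, 0, 0.01)
    ## pass 1: accumulate the polygenic score, recording RNG states
    x1 <- rbinom(n, 2L, maf[1L])
    chunks <- split(seq(2L, m), ceiling(seq_len(m - 1L) / chunk_size))
    states <- vector("list", length(chunks))
    G <- numeric(n)
    for (i in seq_along(chunks)) {
      states[[i]] <- .Random.seed
      Xc <- cpp_binom2_matrix(n, maf[chunks[[i]]])
      G <- G + drop(Xc %*% beta_bg[chunks[[i]] - 1L])
    }
    built <- .build_traits(as.numeric(x1), G, cfg)
    Y <- built$traits
    for (k in seq_len(cfg$r)) Y[, k] <- scale_component(Y[, k])
    E0 <- sweep(Y, 2L, colMeans(Y))
    after_traits <- .Random.seed
    ## pass 2: replay each chunk and scan
    h0 <- rep.int(1 / n, n)
    sc1 <- cpp_lit_scan(E0, matrix(as.numeric(x1)), TRUE, TRUE, 1e-10, h0)
    res <- vector("list", length(chunks) + 1L)
    res[[1L]] <- .scan_pvalues(sc1)
    for (i in seq_along(chunks)) {
      assign(".Random.seed", states[[i]], envir = .GlobalEnv)
      Xc <- cpp_binom2_matrix(n, maf[chunks[[i]]])
      sc <- cpp_lit_scan(E0, Xc, TRUE, TRUE, 1e-10, h0)
      res[[i + 1L]] <- .scan_pvalues(sc)
    }
    assign(".Random.seed", after_traits, envir = .GlobalEnv)
    pv[[d]] <- do.call(rbind, res)
  }
  pvals <- do.call(rbind, pv)
  methods <- c("p_wlit", "p_ulit", "p_alit")
  n_tests <- sum(!is.na(pvals[, "p_alit"]))
  counts <- vapply(methods, function(m2)
    sum(pvals[, m2] < alpha, na.rm = TRUE), numeric(1))
  ci <- qbinom(c(0.025, 0.975), n_tests, alpha)
  structure(list(alpha = alpha, n_tests = n_tests, counts = counts,
                 rates = counts / n_tests,
                 ci_count = ci, ci_rate = ci / n_tests,
                 pvalues = pvals),
            class = "type1_result")
}

#' @export
print.type1_result <- function(x, ...) {
  cat("Type-I error at alpha =", format(x$alpha), "over", x$n_tests,
      "tests\n")
  for (m in names(x$counts))
    cat(sprintf("  %s: %.2e (%d rejections)\n", sub("p_", "", m),
                x$rates[[m]], x$counts[[m]]))
  cat("95% binomial interval for the rate: [",
      format(x$ci_rate[1L], digits = 3), ", ",
      format(x$ci_rate[2L], digits = 3), "]\n", sep = "")
  invisible(x)
}
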