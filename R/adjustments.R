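## Robustness layer: genomic-control adjustment, additive cross-trait
## (LD) adjustment, 2-df dominance/scale adjustment, and individual-specific
## allele-frequency standardization.

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364` (the 1-df chi-squared
#' median). Values above 1 indicate test-statistic inflation from
#' unmodelled structure or pervasive polygenic signal.
#'
#' @param pvalues p-values in (0, 1]; fewer than 100 triggers a warning
#'   (the median becomes noisy) but the factor is still computed.
#' @return positive scalar.
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  if (length(p) < 100L)
    warning("genomic inflation estimated from fewer than 100 p-values")
  if (!length(p)) stop("no finite p-values")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Genomic-control adjustment of p-values
#'
#' Deflates each 1-df chi-squared quantile by `lambda_gc` and maps back to
#' a p-value: `p_adj = P(chi^2_1 > qchisq(1 - p, 1) / lambda)`. A factor
#' below 1 leaves p-values unchanged (deflation is never used to inflate
#' significance). Monotone, so rank order is preserved. Applied to the
#' wLIT and uLIT p-values *before* Cauchy combination.
#'
#' @param pvalues p-values in (0, 1].
#' @param lambda_gc genomic inflation factor.
#' @return adjusted p-values.
#' @export
gc_adjust <- function(pvalues, lambda_gc) {
  if (!is.finite(lambda_gc) || lambda_gc <= 0) stop("invalid lambda_gc")
  if (lambda_gc <= 1) return(pvalues)
  chisq <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  pchisq(chisq / lambda_gc, df = 1, lower.tail = FALSE)
}

#' Per-method inflation report
#'
#' Genomic inflation factors of the wLIT and uLIT p-value sets, optionally
#' stratified by minor-allele-frequency bins, serializable as JSON.
#'
#' @param p_wlit,p_ulit p-value vectors.
#' @param maf optional per-SNP minor allele frequencies for binning.
#' @param maf_breaks bin boundaries used when `maf` is given.
#' @param json_path optional path; when supplied and the jsonlite package
#'   is available the report is written there as JSON.
#' @return list of class `"inflation_report"`.
#' @export
inflation_report <- function(p_wlit, p_ulit, maf = NULL,
                             maf_breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                             json_path = NULL) {
  rep_ <- list(lambda_gc = c(wlit = genomic_inflation(p_wlit),
                             ulit = genomic_inflation(p_ulit)),
               n_snps_used = length(p_wlit))
  if (!is.null(maf)) {
    bins <- cut(maf, maf_breaks, include.lowest = TRUE)
    rep_$maf_bins <- vapply(levels(bins), function(b) {
      i <- which(bins == b)
      if (length(i) < 100L) return(NA_real_)
      genomic_inflation(p_wlit[i])
    }, numeric(1))
  }
  class(rep_) <- "inflation_report"
  if (!is.null(json_path) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(unclass(rep_), json_path, auto_unbox = TRUE,
                         digits = NA)
  rep_
}

#' @export
print.inflation_report <- function(x, ...) {
  cat("Genomic inflation (", x$n_snps_used, " SNPs): wLIT ",
      format(x$lambda_gc[["wlit"]], digits = 4), ", uLIT ",
      format(x$lambda_gc[["ulit"]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cross-trait additive-effect kernel test
#'
#' Kernel independence test between the traits themselves (not their
#' SQ/CP transforms) and an adjusted SNP: the multivariate additive
#' association test used to flag neighboring SNPs whose additive effects
#' could masquerade as interaction signal. With a single trait it reduces
#' to the squared-correlation (score) test.
#'
#' @param traits trait matrix residualized on covariates/structure but
#'   *not* on the tested SNP (a matrix or `"lit_residuals"` object).
#' @param x_adj mean-zero adjusted genotype vector.
#' @param kernel `"linear"` (eigenvalue-weighted) or `"projection"`.
#' @param rank_tol relative eigenvalue cutoff.
#' @return p-value with attributes `T`, `d1`, `d2`.
#' @export
additive_cross_trait_test <- function(traits, x_adj,
                                      kernel = c("linear", "projection"),
                                      rank_tol = 1e-10) {
  kernel <- match.arg(kernel)
  if (inherits(traits, "lit_residuals")) traits <- traits$residuals
  Y <- sweep(as.matrix(traits), 2L, colMeans(as.matrix(traits)))
  n <- nrow(Y)
  Yf <- spectral_factorize(Y, rank_tol)
  xx <- sum(x_adj^2)
  if (xx < 1e-12 * n) stop("monomorphic or fully-explained SNP")
  a <- drop(crossprod(Yf$vectors, x_adj))
  if (kernel == "linear") {
    T_ <- sum(Yf$values * a^2) / n
    p <- weighted_chisq_sf(T_, Yf$values * xx / (n * (n - 1)))
  } else {
    T_ <- sum(a^2) / (n * xx)
    p <- pchisq(n * (n - 1) * T_, df = Yf$d, lower.tail = FALSE)
  }
  structure(min(1, max(1e-300, p)), T = T_, d1 = Yf$d, d2 = 1L)
}

#' Re-test a lead SNP after regressing out additive LD neighbors
#'
#' Identifies neighboring SNPs correlated with the lead SNP beyond
#' `r_threshold`, tests each for multivariate additive effects with
#' [additive_cross_trait_test()], regresses significant neighbors out of
#' the traits jointly, and reruns the latent-interaction test at the lead
#' SNP. Removes false-positive interaction signal manufactured by
#' imperfectly-corrected additive effects in linkage disequilibrium.
#'
#' @param traits standardized trait matrix.
#' @param lead dosage vector of the lead SNP.
#' @param neighbors n x q dosage matrix of SNPs within the LD window
#'   (e.g. 1 Mb).
#' @param covariates optional covariate/structure matrix.
#' @param r_threshold absolute correlation defining LD with the lead SNP.
#' @param alpha significance level for the additive neighbor test.
#' @param studentize logical, studentize residuals before the SQ/CP step.
#' @return `"lit_result"` row with columns `n_ld_neighbors` (tested) and
#'   `n_regressed` (significant and removed); when no neighbor qualifies
#'   the unadjusted result is returned with `n_regressed = 0`.
#' @export
ld_adjust_retest <- function(traits, lead, neighbors = NULL,
                             covariates = NULL, r_threshold = 0.1,
                             alpha = 5e-8, studentize = TRUE) {
  traits <- as.matrix(traits)
  x_lead <- adjust_genotype(lead, covariates)
  base_res <- residualize(traits, covariates)
  sig <- integer(0)
  q <- 0L
  if (!is.null(neighbors)) {
    neighbors <- as.matrix(neighbors)
    q <- ncol(neighbors)
    rr <- abs(apply(neighbors, 2L, function(g)
      cor(adjust_genotype(g, covariates), x_lead)))
    cand <- which(rr > r_threshold)
    sig <- cand[vapply(cand, function(j) {
      additive_cross_trait_test(base_res,
                                adjust_genotype(neighbors[, j], covariates)) < alpha
    }, logical(1))]
  }
  covs2 <- covariates
  if (length(sig))
    covs2 <- cbind(if (!is.null(covariates)) as.matrix(covariates),
                   neighbors[, sig, drop = FALSE])
  res <- residualize(traits, covs2, genotype = lead)
  if (studentize) res <- studentize_residuals(res)
  Z <- compute_sqcp(res, include_cp = ncol(traits) >= 2L)
  out <- lit_single_snp(Z, adjust_genotype(lead, covs2))
  out$n_ld_neighbors <- q
  out$n_regressed <- length(sig)
  out
}

#' Re-test a SNP after removing dominance / trait-scale effects
#'
#' Residualizes the traits with the 2-df genotypic coding (separate means
#' for one and two minor alleles), absorbing any genotype-level mean
#' function — dominance or scale misspecification — before the
#' latent-interaction test is rerun on the adjusted genotype.
#'
#' @param traits standardized trait matrix.
#' @param genotype dosage vector with at least two observed levels.
#' @param covariates optional covariate/structure matrix.
#' @param studentize logical.
#' @return `"lit_result"` row.
#' @export
dominance_retest <- function(traits, genotype, covariates = NULL,
                             studentize = TRUE) {
  g <- round(as.numeric(genotype))
  lev <- unique(g[!is.na(g)])
  if (length(lev) < 2L) stop("genotype has fewer than 2 observed levels")
  dom <- length(lev) >= 3L   # with 2 levels the 2-df coding is collinear
  res <- residualize(as.matrix(traits), covariates, genotype = g,
                     dominance = dom)
  if (studentize) res <- studentize_residuals(res)
  Z <- compute_sqcp(res, include_cp = ncol(as.matrix(traits)) >= 2L)
  lit_single_snp(Z, adjust_genotype(genotype, covariates))
}

#' Genotype standardization by individual-specific allele frequencies
#'
#' Fits a per-SNP logistic regression of allele counts on the structure
#' axes to obtain individual-specific allele frequencies `pi_j`, then
#' standardizes `x_j` to `(x_j - 2 pi_j) / sqrt(2 pi_j (1 - pi_j))`,
#' removing both mean and variance effects of structure. With no axes
#' this reduces to the usual allele-frequency standardization. Intended
#' for datasets of modest size (one GLM per SNP).
#'
#' @param genotype dosage vector in `[0, 2]`.
#' @param structure_axes optional n x k matrix of structure axes.
#' @param eps fitted frequencies outside `(eps, 1 - eps)` are clipped with
#'   a warning.
#' @return standardized genotype vector with attribute `"iaf"`.
#' @export
iaf_standardize <- function(genotype, structure_axes = NULL, eps = 1e-3) {
  x <- as.numeric(genotype)
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (var(x) == 0) stop("monomorphic SNP cannot be standardized")
  if (is.null(structure_axes)) {
    pihat <- rep.int(mean(x) / 2, length(x))
  } else {
    h <- as.matrix(structure_axes)
    fit <- stats::glm.fit(cbind(1, h), x / 2, weights = rep.int(2, length(x)),
                          family = stats::binomial())
    pihat <- fit$fitted.values
  }
  if (any(pihat < eps | pihat > 1 - eps)) {
    warning("fitted allele frequencies clipped to (", eps, ", ", 1 - eps, ")")
    pihat <- pmin(1 - eps, pmax(eps, pihat))
  }
  structure((x - 2 * pihat) / sqrt(2 * pihat * (1 - pihat)), iaf = pihat)
}
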