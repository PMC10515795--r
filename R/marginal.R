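## Baseline univariate procedures: Marginal (SQ) and Marginal (SQ/CP) with
## the principal-component Bonferroni correction.

#' Effective number of tests from principal components
#'
#' Smallest number of principal components of the column-standardized
#' SQ/CP matrix whose cumulative variance fraction reaches `threshold`.
#' Used as the Bonferroni divisor K for the marginal procedures
#' (correlation scale, so the count is unit-invariant).
#'
#' @param Z SQ/CP matrix (or any feature matrix with >= 1 non-constant
#'   column).
#' @param threshold cumulative variance fraction, default 0.95.
#' @return integer K >= 1.
#' @export
effective_tests_K <- function(Z, threshold = 0.95) {
  Z <- as.matrix(Z)
  v <- apply(Z, 2L, var)
  Z <- Z[, v > 0, drop = FALSE]
  if (!ncol(Z)) stop("no non-constant columns")
  ev <- eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  as.integer(which(cumsum(ev) / sum(ev) >= threshold - 1e-12)[1L])
}

#' Marginal association tests of SQ/CP columns against a SNP
#'
#' Regresses every column of the SQ/CP matrix on the adjusted genotype,
#' takes the minimum p-value, and compares it to `alpha / K` with K the
#' number of principal components explaining 95% of the matrix variation.
#' With a SQ-only matrix (from `compute_sqcp(..., include_cp = FALSE)`)
#' this is the Marginal (SQ) procedure; with cross products included it is
#' Marginal (SQ/CP). Per-column p-values use the large-sample score test
#' `z = sqrt(n) * cor(z_col, x)` by default; `exact_t = TRUE` uses the
#' exact t reference for small n.
#'
#' @param Z centered SQ/CP matrix.
#' @param x_adj mean-zero adjusted genotype vector.
#' @param alpha familywise significance level.
#' @param exact_t logical; use the t distribution with n - 2 df.
#' @param K optional precomputed effective test count (per-dataset reuse).
#' @return object of class `"marginal_result"`: list with `p_values`
#'   (named per column), `min_p`, `K`, `alpha_prime`, `significant`,
#'   `best_column`, `n`.
#' @export
marginal_test <- function(Z, x_adj, alpha = 5e-8, exact_t = FALSE, K = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (length(x_adj) != n) stop("genotype length does not match Z")
  nm <- colnames(Z)
  if (is.null(nm)) nm <- paste0("col", seq_len(ncol(Z)))
  sx <- sqrt(sum(x_adj^2))
  zc <- sweep(Z, 2L, colMeans(Z))
  sz <- sqrt(colSums(zc^2))
  const <- sz == 0 | sx == 0
  if (any(const)) warning("constant column(s): ",
                          paste(nm[const], collapse = ", "),
                          "; p-value set to 1")
  rho <- rep.int(0, ncol(Z))
  rho[!const] <- drop(crossprod(zc[, !const, drop = FALSE], x_adj)) /
    (sz[!const] * sx)
  rho <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  if (exact_t) {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    p <- 2 * pnorm(-abs(rho) * sqrt(n))
  }
  p[const] <- 1
  names(p) <- nm
  if (is.null(K)) K <- effective_tests_K(Z)
  min_p <- min(p)
  structure(list(p_values = p, min_p = min_p, K = as.integer(K),
                 alpha_prime = alpha / K,
                 significant = min_p < alpha / K,
                 best_column = nm[which.min(p)], n = n),
            class = "marginal_result")
}

#' @export
print.marginal_result <- function(x, ...) {
  cat("Marginal SQ/CP association test (", length(x$p_values),
      " columns, n = ", x$n, ")\n", sep = "")
  cat("  min p = ", format(x$min_p, digits = 4),
      " at ", x$best_column, "\n", sep = "")
  cat("  K = ", x$K, ", alpha' = ", format(x$alpha_prime, digits = 4),
      " -> ", if (x$significant) "significant" else "not significant",
      "\n", sep = "")
  invisible(x)
}
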