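## Step 1 of the LIT pipeline: trait standardization and residualization of
## additive genetic, covariate, and population-structure effects.

#' Standardize traits, optionally within groups
#'
#' Centers and scales each trait column to mean 0, standard deviation 1
#' (sample convention, divisor `n - 1`). When `groups` is supplied the
#' transformation is applied within each group separately, as is standard
#' when traits are standardized by sex. Optionally removes samples whose
#' value lies more than `outlier_sd` standard deviations *above* the group
#' mean in any trait before standardizing.
#'
#' @param raw numeric matrix (samples x traits) or data frame of traits.
#' @param groups optional length-n vector of group labels (e.g. sex).
#' @param outlier_sd optional positive scalar; samples exceeding
#'   `mean + outlier_sd * sd` in any trait (within group) are dropped before
#'   standardization. `NULL` (default) keeps all samples.
#' @return numeric matrix of standardized traits; dropped samples (if any)
#'   are removed and recorded in the `"dropped"` attribute.
#' @examples
#' y <- cbind(a = rnorm(100, 10, 2), b = rnorm(100, -3, 5))
#' ys <- standardize_traits(y)
#' round(colMeans(ys), 10)
#' @export
standardize_traits <- function(raw, groups = NULL, outlier_sd = NULL) {
  y <- as.matrix(raw)
  storage.mode(y) <- "double"
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(ncol(y)))
  if (anyNA(y)) stop("traits contain missing values; align/drop samples first")
  if (is.null(groups)) groups <- rep.int(1L, nrow(y))
  if (length(groups) != nrow(y)) stop("length(groups) != nrow(traits)")
  g <- factor(groups)
  if (any(table(g) < 2L)) stop("each group must contain at least 2 samples")
  keep <- rep.int(TRUE, nrow(y))
  if (!is.null(outlier_sd)) {
    for (lev in levels(g)) {
      idx <- which(g == lev)
      for (k in seq_len(ncol(y))) {
        v <- y[idx, k]
        keep[idx[v > mean(v) + outlier_sd * sd(v)]] <- FALSE
      }
    }
    y <- y[keep, , drop = FALSE]
    g <- g[keep]
  }
  for (lev in levels(g)) {
    idx <- which(g == lev)
    for (k in seq_len(ncol(y))) {
      v <- y[idx, k]
      s <- sd(v)
      if (!is.finite(s) || s == 0)
        stop("trait '", colnames(y)[k], "' is constant",
             if (nlevels(g) > 1L) paste0(" within group '", lev, "'"))
      y[idx, k] <- (v - mean(v)) / s
    }
  }
  attr(y, "dropped") <- which(!keep)
  y
}

# Build the joint design matrix: intercept + covariates + genotype coding.
# dominance = TRUE codes the SNP as two indicators (x == 1, x == 2).
.design_matrix <- function(n, covariates = NULL, genotype = NULL,
                           dominance = FALSE) {
  cols <- list(`(Intercept)` = rep.int(1, n))
  if (!is.null(covariates)) {
    h <- as.matrix(covariates)
    if (nrow(h) != n) stop("covariate rows do not match sample count")
    if (is.null(colnames(h))) colnames(h) <- paste0("H", seq_len(ncol(h)))
    for (k in seq_len(ncol(h))) cols[[colnames(h)[k]]] <- h[, k]
  }
  if (!is.null(genotype)) {
    x <- as.numeric(genotype)
    if (length(x) != n) stop("genotype length does not match sample count")
    if (dominance) {
      cols[["geno1"]] <- as.numeric(x == 1)
      cols[["geno2"]] <- as.numeric(x == 2)
    } else {
      cols[["geno"]] <- x
    }
  }
  do.call(cbind, cols)
}

#' Residualize traits on covariates and (optionally) a SNP
#'
#' Least-squares residuals of each trait on an implicit intercept, the
#' covariate/structure columns, and optionally the genotype, coded either
#' additively (one dosage column) or as a 2-df genotypic model (indicator
#' columns for one and two minor alleles) to absorb dominance or
#' trait-scale effects.
#'
#' @param traits numeric matrix (samples x traits), typically from
#'   [standardize_traits()].
#' @param covariates optional numeric matrix of measured covariates and/or
#'   population-structure axes.
#' @param genotype optional numeric dosage vector in `[0, 2]`.
#' @param dominance logical; code the genotype with the 2-df genotypic
#'   model instead of a single additive column.
#' @return object of class `"lit_residuals"`: list with `residuals`
#'   (n x r), `hat_diag` (leverages of the joint design), `dof` (residual
#'   degrees of freedom), and `rank`.
#' @export
residualize <- function(traits, covariates = NULL, genotype = NULL,
                        dominance = FALSE) {
  y <- as.matrix(traits)
  storage.mode(y) <- "double"
  n <- nrow(y)
  d <- .design_matrix(n, covariates, genotype, dominance)
  qd <- qr(d)
  if (qd$rank < ncol(d)) {
    bad <- colnames(d)[qd$pivot[(qd$rank + 1L):ncol(d)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  e <- qr.resid(qd, y)
  q1 <- qr.Q(qd)
  h <- rowSums(q1^2)
  structure(list(residuals = e, hat_diag = h, dof = n - qd$rank,
                 rank = qd$rank),
            class = "lit_residuals")
}

#' Adjust a genotype vector for population structure
#'
#' Residual of the dosage on an intercept plus the supplied structure
#' columns; with no structure columns this is plain mean-centering.
#' Missing dosages are mean-imputed first.
#'
#' @param genotype numeric dosage vector in `[0, 2]` (NA allowed).
#' @param covariates optional matrix of structure axes (e.g. principal
#'   components).
#' @return mean-zero adjusted dosage vector.
#' @export
adjust_genotype <- function(genotype, covariates = NULL) {
  x <- as.numeric(genotype)
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (is.null(covariates)) return(x - mean(x))
  d <- .design_matrix(length(x), covariates)
  qd <- qr(d)
  if (qd$rank < ncol(d)) stop("structure design is rank deficient")
  drop(qr.resid(qd, matrix(x)))
}

#' Studentize residuals by design leverage
#'
#' Divides each residual by `sqrt(1 - h_jj)` (internal studentization with
#' the hat diagonal of the joint design) so that squared residuals and
#' cross products are unbiased estimates of the individual-specific trait
#' variances and covariances, then re-centers the columns.
#'
#' @param res a `"lit_residuals"` object from [residualize()].
#' @param tol leverage values above `1 - tol` are exact-fit points and
#'   raise an error.
#' @return a `"lit_residuals"` object with studentized, re-centered
#'   residuals (`hat_diag` is retained).
#' @export
studentize_residuals <- function(res, tol = 1e-8) {
  stopifnot(inherits(res, "lit_residuals"))
  h <- res$hat_diag
  if (any(h >= 1 - tol))
    stop("leverage >= 1 at sample(s) ", paste(which(h >= 1 - tol), collapse = ", "),
         "; residual is an exact fit there")
  e <- res$residuals / sqrt(1 - h)
  e <- sweep(e, 2L, colMeans(e))
  res$residuals <- e
  res$studentized <- TRUE
  res
}

#' Top principal components of a genotype matrix
#'
#' Structure axes computed from column-standardized dosages (mean-imputed),
#' for use as covariates in [residualize()] and [adjust_genotype()].
#'
#' @param X dosage matrix (samples x SNPs).
#' @param k number of components.
#' @return n x k matrix of principal-component scores.
#' @export
genotype_pcs <- function(X, k = 10L) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (anyNA(x)) X[is.na(x), j] <- mean(x, na.rm = TRUE)
  }
  s <- scale(X)
  s[, !is.finite(colSums(s))] <- 0
  k <- min(k, nrow(X) - 1L, ncol(X))
  pr <- svd(s, nu = k, nv = 0)
  sweep(pr$u, 2L, pr$d[seq_len(k)], `*`)
}
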