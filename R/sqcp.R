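## Step 2: individual-specific trait variance (SQ) and covariance (CP)
## estimates from trait residuals.

#' Squared residuals and pairwise cross products
#'
#' Builds the n x (r + r(r-1)/2) matrix `Z = [Z_SQ, Z_CP]` whose SQ columns
#' are elementwise squares of the residual columns (individual-specific
#' trait variance estimates) and whose CP columns are elementwise products
#' of residual pairs in lexicographic order (1,2), (1,3), ..., (r-1,r)
#' (individual-specific covariance estimates).
#'
#' @param residuals numeric residual matrix (samples x traits) or a
#'   `"lit_residuals"` object.
#' @param include_cp logical; include the cross-product columns (requires
#'   at least two traits).
#' @param center logical; mean-center each column (required before kernel
#'   construction).
#' @return numeric matrix with a `"column_kinds"` attribute labelling each
#'   column `SQ:<k>` or `CP:<k>.<k'>`, and a `"centered"` attribute.
#' @examples
#' e <- cbind(rnorm(20), rnorm(20))
#' z <- compute_sqcp(e)
#' attr(z, "column_kinds")
#' @export
compute_sqcp <- function(residuals, include_cp = TRUE, center = TRUE) {
  if (inherits(residuals, "lit_residuals")) residuals <- residuals$residuals
  e <- as.matrix(residuals)
  r <- ncol(e)
  if (r < 1L) stop("need at least one trait")
  if (include_cp && r < 2L)
    stop("cross products require at least two traits (r >= 2)")
  nm <- colnames(e)
  if (is.null(nm)) nm <- as.character(seq_len(r))
  z <- e * e
  kinds <- paste0("SQ:", nm)
  if (include_cp && r >= 2L) {
    pairs <- which(upper.tri(diag(r)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    zcp <- e[, pairs[, 1L], drop = FALSE] * e[, pairs[, 2L], drop = FALSE]
    z <- cbind(z, zcp)
    kinds <- c(kinds, paste0("CP:", nm[pairs[, 1L]], ".", nm[pairs[, 2L]]))
  }
  colnames(z) <- kinds
  if (center) z <- sweep(z, 2L, colMeans(z))
  attr(z, "column_kinds") <- kinds
  attr(z, "centered") <- center
  z
}

#' Quadratic-in-genotype coefficients of the conditional trait moments
#'
#' Under the single-SNP latent-interaction model
#' `Y_k = beta_k X + phi_k M + gamma_k M X + eps_k` with `M` standard
#' normal, the conditional variance of trait k given genotype is the
#' quadratic `a + b X + c X^2` with `a = phi^2 + sigma^2`,
#' `b = 2 phi gamma`, `c = gamma^2`; the conditional covariance of traits
#' k and k' is `a~ + b~ X + c~ X^2` with `a~ = phi phi'`,
#' `b~ = phi gamma' + phi' gamma`, `c~ = gamma gamma'`. Used as the
#' reference when validating the simulator's moment structure.
#'
#' @param phi,gamma,sigma environment, interaction, and noise parameters of
#'   trait k (`sigma >= 0`).
#' @param phi2,gamma2 optional parameters of a second trait k'.
#' @return named list with `a`, `b`, `c` and, when a second trait is given,
#'   `a_tilde`, `b_tilde`, `c_tilde`.
#' @export
itv_itc_coefficients <- function(phi, gamma, sigma, phi2 = NULL, gamma2 = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  out <- list(a = phi^2 + sigma^2, b = 2 * phi * gamma, c = gamma^2)
  if (!is.null(phi2)) {
    out$a_tilde <- phi * phi2
    out$b_tilde <- phi * gamma2 + phi2 * gamma
    out$c_tilde <- gamma * gamma2
  }
  out
}

#' Write a SQ/CP matrix to a delimited file
#'
#' Debug writer: the Z matrix with its column-kind headers.
#'
#' @param z matrix from [compute_sqcp()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_sqcp <- function(z, path, sep = "\t") {
  write.table(z, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
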