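# Shared fixtures and independent oracles used across test files.

# Dense-kernel oracle: (1/n) tr(K L) with explicitly formed n x n linear
# kernels from centered feature matrices.
dense_trace_T <- function(Z, x) {
  n <- nrow(as.matrix(Z))
  K <- tcrossprod(as.matrix(x))
  L <- tcrossprod(as.matrix(Z))
  sum(diag(K %*% L)) / n
}

# Normal-equations oracle for least-squares residuals.
normal_eq_residuals <- function(y, D) {
  y - D %*% solve(crossprod(D), crossprod(D, y))
}

# Small correlated multi-trait dataset with one interacting SNP; cheap
# enough for repeated use.
toy_dataset <- function(n = 500, r = 3, m = 10, tau = 1,
                        baseline_corr = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_lit_data(sim_config(n = n, r = r, m = m,
                               baseline_corr = baseline_corr, tau = tau))
}

# Centered SQ/CP matrix plus adjusted genotype for a toy dataset.
toy_Z_x <- function(d, snp = 1, studentize = TRUE) {
  res <- residualize(standardize_traits(d$traits),
                     genotype = d$genotypes[, snp])
  if (studentize) res <- studentize_residuals(res)
  list(Z = compute_sqcp(res, include_cp = ncol(d$traits) >= 2),
       x = adjust_genotype(d$genotypes[, snp]))
}
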