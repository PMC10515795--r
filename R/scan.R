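## Genome-scan driver: the main user entry point tying the three pipeline
## steps together across all SNPs, with chunked execution.

#' Latent-interaction genome scan
#'
#' Fits the full pipeline for every SNP: standardize traits (optionally
#' within groups), residualize on covariates/structure, then per SNP
#' remove the additive genetic effect (via the Frisch-Waugh-Lovell
#' identity, so the result equals a joint refit), studentize, build the
#' squared-residual / cross-product matrix, and run the kernel
#' independence tests (wLIT, uLIT) with Cauchy aggregation (aLIT).
#' Optionally adds the marginal minimum-p procedures and a post-hoc
#' genomic-control adjustment (applied to the wLIT and uLIT p-values
#' before recombination).
#'
#' Genotypes are processed in chunks of `chunk_size` SNPs so peak memory
#' is O(n (r + s) + n chunk); results are returned in input order
#' regardless of scheduling.
#'
#' @param traits numeric matrix or data frame (samples x traits).
#' @param genotypes dosage matrix (samples x SNPs) or a
#'   `"plink_accessor"` from [read_plink()]; dosages in `[0, 2]`, NA
#'   mean-imputed per SNP.
#' @param covariates optional covariate / structure matrix.
#' @param groups optional grouping for trait standardization (e.g. sex).
#' @param include_cp include cross-product columns (`FALSE` gives the
#'   cheaper SQ-only mode).
#' @param studentize studentize residuals by design leverage.
#' @param marginal also run the marginal minimum-p procedures per SNP.
#' @param gc_correct apply genomic-control adjustment to the wLIT/uLIT
#'   p-values (then recombine aLIT).
#' @param alpha significance threshold recorded in the result.
#' @param rank_tol relative eigenvalue cutoff.
#' @param chunk_size SNPs per chunk.
#' @param workers number of worker processes for chunk execution
#'   (forked via the parallel package); results are assembled in input
#'   order, so the output is identical for any worker count.
#' @param snp_info optional data frame with per-SNP `snp_id`, `chrom`,
#'   `pos` (taken from the accessor when available).
#' @param outlier_sd optional outlier cut passed to
#'   [standardize_traits()].
#' @return object of class `"lit_scan"`: a data frame with one row per
#'   SNP (`snp_id`, `chrom`, `pos`, `maf`, `n`, `d1`, `d2`, `T_wlit`,
#'   `p_wlit`, `T_ulit`, `p_ulit`, `p_alit`, and marginal columns when
#'   requested) carrying the run metadata in attributes.
#' @examples
#' set.seed(1)
#' d <- simulate_lit_data(sim_config(n = 600, r = 3, m = 20,
#'                                   baseline_corr = 0.25, tau = 1))
#' sc <- lit(d$traits, d$genotypes)
#' head(sc)
#' @export
lit <- function(traits, genotypes, covariates = NULL, groups = NULL,
                include_cp = TRUE, studentize = TRUE, marginal = FALSE,
                gc_correct = FALSE, alpha = 5e-8, rank_tol = 1e-10,
                chunk_size = 1000L, workers = 1L, snp_info = NULL,
                outlier_sd = NULL) {
  acc <- NULL
  if (inherits(genotypes, "plink_accessor")) {
    acc <- genotypes
    m <- acc$m
    if (is.null(snp_info)) snp_info <- acc$bim[, c("snp_id", "chrom", "pos")]
  } else {
    genotypes <- as.matrix(genotypes)
    m <- ncol(genotypes)
    if (is.null(snp_info))
      snp_info <- data.frame(snp_id = if (!is.null(colnames(genotypes)))
                               colnames(genotypes)
                             else paste0("snp", seq_len(m)),
                             chrom = NA_integer_, pos = NA_integer_)
  }
  if (m == 0L) {
    warning("no SNPs to test (empty set after QC?)")
    out <- data.frame(snp_id = character(0))
    class(out) <- c("lit_scan", "data.frame")
    return(out)
  }
  ys <- standardize_traits(traits, groups = groups, outlier_sd = outlier_sd)
  kept <- setdiff(seq_len(nrow(as.matrix(traits))), attr(ys, "dropped"))
  n <- nrow(ys)
  r <- ncol(ys)
  covk <- if (!is.null(covariates)) as.matrix(covariates)[kept, , drop = FALSE]
  base <- residualize(ys, covk)
  E0 <- sweep(base$residuals, 2L, colMeans(base$residuals))
  h0 <- base$hat_diag
  qd <- qr(.design_matrix(n, covk))
  chunks <- split(seq_len(m), ceiling(seq_len(m) / chunk_size))
  run_chunk <- function(idx) {
    Xc <- if (!is.null(acc)) get_dosages(acc, idx)
          else genotypes[kept, idx, drop = FALSE]
    maf <- colMeans(Xc, na.rm = TRUE) / 2
    maf <- pmin(maf, 1 - maf)
    if (!is.null(covk)) {
      for (j in seq_len(ncol(Xc))) {
        x <- Xc[, j]
        if (anyNA(x)) Xc[is.na(x), j] <- mean(x, na.rm = TRUE)
      }
      Xc <- qr.resid(qd, Xc)
    }
    sc <- cpp_lit_scan(E0, Xc, include_cp, studentize, rank_tol, h0)
    pv <- .scan_pvalues(sc)
    out <- data.frame(snp_info[idx, , drop = FALSE], maf = maf, n = n,
                      d1 = as.integer(sc$d1), d2 = 1L, pv,
                      stringsAsFactors = FALSE)
    out$d2[out$d1 <= 0L] <- 0L
    if (marginal) {
      mm <- t(vapply(seq_along(idx), function(s) {
        if (sc$d1[s] <= 0L) return(c(NA_real_, NA_real_, NA_real_))
        msq <- .marginal_pcols(sc$v[s, ], sc$cdiag[s, ], sc$xx[s], n)
        c(min(msq), min(msq[seq_len(r)]), which.min(msq))
      }, numeric(3)))
      out$min_p_sqcp <- mm[, 1L]
      out$min_p_sq <- mm[, 2L]
      out$best_column <- mm[, 3L]
    }
    out
  }
  rows <- if (workers > 1L)
    parallel::mclapply(chunks, run_chunk, mc.cores = workers)
  else lapply(chunks, run_chunk)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (marginal) {
    # per-dataset effective test counts from the covariate-only residuals
    Zb <- compute_sqcp(if (studentize) studentize_residuals(base) else base,
                       include_cp = include_cp)
    res_attr_K_sqcp <- effective_tests_K(Zb)
    res_attr_K_sq <- if (include_cp) effective_tests_K(Zb[, seq_len(r)])
                     else res_attr_K_sqcp
    res$sig_marg_sqcp <- res$min_p_sqcp < alpha / res_attr_K_sqcp
    res$sig_marg_sq <- res$min_p_sq < alpha / res_attr_K_sq
    attr(res, "K_sqcp") <- res_attr_K_sqcp
    attr(res, "K_sq") <- res_attr_K_sq
  }
  if (gc_correct) {
    ok <- !is.na(res$p_wlit)
    lam <- c(wlit = genomic_inflation(res$p_wlit[ok]),
             ulit = genomic_inflation(res$p_ulit[ok]))
    res$p_wlit_gc <- gc_adjust(res$p_wlit, lam[["wlit"]])
    res$p_ulit_gc <- gc_adjust(res$p_ulit, lam[["ulit"]])
    res$p_alit_gc <- NA_real_
    res$p_alit_gc[ok] <- vapply(which(ok), function(i)
      cauchy_combine(c(res$p_wlit_gc[i], res$p_ulit_gc[i])), numeric(1))
    attr(res, "lambda_gc") <- lam
  }
  attr(res, "alpha") <- alpha
  attr(res, "include_cp") <- include_cp
  attr(res, "n_traits") <- r
  class(res) <- c("lit_scan", "data.frame")
  res
}

## Per-column marginal p-values from the scan cross products.
.marginal_pcols <- function(v, cdiag, xx, n) {
  ok <- cdiag > 0
  rho <- rep.int(0, length(v))
  rho[ok] <- v[ok] / sqrt(cdiag[ok] * xx)
  rho <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  p <- 2 * pnorm(-abs(rho) * sqrt(n))
  p[!ok] <- 1
  p
}

#' Write scan results to a delimited file
#'
#' @param x a `"lit_scan"`.
#' @param path output path.
#' @param sep separator.
#' @export
write_lit_scan <- function(x, path, sep = "\t") {
  y <- as.data.frame(x)
  for (cn in grep("^p_", colnames(y), value = TRUE))
    y[[cn]] <- formatC(y[[cn]], format = "e", digits = 5)
  write.table(y, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.lit_scan <- function(x, ...) {
  cat("Latent-interaction scan:", nrow(x), "SNPs,",
      attr(x, "n_traits"), "traits",
      if (!attr(x, "include_cp")) "(SQ-only mode)", "\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4L)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more SNPs\n")
  invisible(x)
}

#' @export
summary.lit_scan <- function(object, alpha = attr(object, "alpha"), ...) {
  p <- object$p_alit
  ok <- !is.na(p)
  lam <- if (sum(ok) >= 100L)
    c(wlit = genomic_inflation(object$p_wlit[ok]),
      ulit = genomic_inflation(object$p_ulit[ok]))
  cat("Latent-interaction scan of", nrow(object), "SNPs (",
      sum(!ok), "skipped )\n")
  if (!is.null(lam))
    cat("genomic inflation: wLIT", format(lam[["wlit"]], digits = 3),
        ", uLIT", format(lam[["ulit"]], digits = 3), "\n")
  hits <- which(ok & p < alpha)
  cat(length(hits), "SNPs significant at alpha =", format(alpha), "\n")
  if (length(hits)) {
    top <- object[hits[order(p[hits])], , drop = FALSE]
    print.data.frame(head(as.data.frame(top), 10L), digits = 4L)
  }
  invisible(list(lambda_gc = lam, n_significant = length(hits)))
}

#' QQ plot of scan p-values
#'
#' Observed versus expected -log10 p-values for the aggregated test
#' (and optionally the individual kernels).
#'
#' @param x a `"lit_scan"`.
#' @param which p-value column to plot.
#' @param ... passed to [plot()].
#' @export
plot.lit_scan <- function(x, which = "p_alit", ...) {
  p <- sort(x[[which]][!is.na(x[[which]])])
  ex <- -log10(ppoints(length(p)))
  plot(ex, -log10(p), xlab = "expected -log10 p", ylab = "observed -log10 p",
       main = paste("QQ,", which), ...)
  abline(0, 1, col = "red")
  invisible(x)
}
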