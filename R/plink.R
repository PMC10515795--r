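## PLINK 1 binary genotype files (.bed/.bim/.fam), phenotype tables, and
## variant QC.

## 256 x 4 decode table: PLINK1 2-bit codes per byte, low bits first.
## 00 -> 2 copies of allele 1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies.
.plink_decode_table <- function() {
  codes <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  tab <- matrix(NA_real_, 256L, 4L)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1L, k] <- codes[[as.character(v %% 4L)]]
      v <- v %/% 4L
    }
  }
  tab
}

#' Read a PLINK 1 binary fileset
#'
#' Opens a `.bed`/`.bim`/`.fam` triplet (SNP-major mode) and returns a
#' lazy accessor: variant and sample tables are parsed eagerly, genotype
#' bytes are kept packed and decoded per SNP on demand via
#' [get_dosages()]. The magic bytes (0x6C 0x1B) and mode byte (0x01) are
#' verified, as is the file length against the sample count.
#'
#' @param prefix path prefix (without extension).
#' @return object of class `"plink_accessor"`: list with `fam`
#'   (data frame: fid, iid, ...), `bim` (chrom, snp_id, cm, pos, a1, a2),
#'   `n`, `m`, and the packed genotype bytes.
#' @export
read_plink <- function(prefix) {
  bedp <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("missing file: ", f)
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  colnames(fam)[1:2] <- c("fid", "iid")
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  colnames(bim) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  n <- nrow(fam)
  m <- nrow(bim)
  sz <- file.size(bedp)
  bpp <- ceiling(n / 4)
  if (sz != 3 + as.double(bpp) * m)
    stop(".bed size ", sz, " does not match 3 + ceil(n/4) * m = ",
         3 + bpp * m, " (truncated or sample-count mismatch)")
  con <- file(bedp, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic[1:2]), c(0x6cL, 0x1bL)))
    stop("not a PLINK .bed file (magic bytes mismatch)")
  if (as.integer(magic[3L]) != 1L)
    stop("only SNP-major .bed files (mode byte 0x01) are supported")
  bytes <- readBin(con, "raw", bpp * m)
  structure(list(fam = fam, bim = bim, n = n, m = m,
                 bytes = bytes, bpp = bpp,
                 decode = .plink_decode_table()),
            class = "plink_accessor")
}

#' @export
print.plink_accessor <- function(x, ...) {
  cat("PLINK 1 fileset:", x$n, "samples,", x$m, "SNPs\n")
  invisible(x)
}

#' Decode dosages for selected SNPs
#'
#' @param acc a `"plink_accessor"`.
#' @param snps integer indices (or snp_id values) of the SNPs to decode.
#' @return numeric matrix (n x length(snps)) of allele-1 dosages with NA
#'   for missing genotypes.
#' @export
get_dosages <- function(acc, snps = seq_len(acc$m)) {
  stopifnot(inherits(acc, "plink_accessor"))
  if (is.character(snps)) snps <- match(snps, acc$bim$snp_id)
  if (anyNA(snps) || any(snps < 1L | snps > acc$m)) stop("unknown SNP index")
  out <- matrix(NA_real_, acc$n, length(snps))
  for (i in seq_along(snps)) {
    j <- snps[i]
    b <- as.integer(acc$bytes[((j - 1L) * acc$bpp + 1L):(j * acc$bpp)])
    g <- as.vector(t(acc$decode[b + 1L, , drop = FALSE]))
    out[, i] <- g[seq_len(acc$n)]
  }
  colnames(out) <- acc$bim$snp_id[snps]
  out
}

#' Write a dosage matrix as a PLINK 1 fileset
#'
#' @param X numeric matrix (samples x SNPs) of dosages in `{0, 1, 2, NA}`.
#' @param prefix output path prefix.
#' @param sample_ids optional IIDs (defaults to `S1..Sn`).
#' @param bim optional variant table (chrom, snp_id, cm, pos, a1, a2).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(X, prefix, sample_ids = NULL, bim = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(bim))
    bim <- data.frame(chrom = 1L, snp_id = if (!is.null(colnames(X)))
                        colnames(X) else paste0("snp", seq_len(m)),
                      cm = 0, pos = seq_len(m), a1 = "A", a2 = "B")
  write.table(data.frame(sample_ids, sample_ids, 0, 0, 0, -9),
              paste0(prefix, ".fam"), col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  write.table(bim, paste0(prefix, ".bim"), col.names = FALSE,
              row.names = FALSE, quote = FALSE, sep = "\t")
  code <- matrix(1L, n, m)                     # 01 missing
  code[!is.na(X) & X == 2] <- 0L
  code[!is.na(X) & X == 1] <- 2L
  code[!is.na(X) & X == 0] <- 3L
  bpp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep.int(0L, 4L * bpp - n))
    idx <- seq(1L, length(cj), by = 4L)
    byte <- cj[idx] + 4L * cj[idx + 1L] + 16L * cj[idx + 2L] + 64L * cj[idx + 3L]
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read a phenotype / covariate table
#'
#' Tab- or comma-delimited with header; the first column (or FID/IID
#' pair) holds sample identifiers, which become row names.
#'
#' @param path file path.
#' @return data frame keyed by sample ID.
#' @export
read_pheno <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  idc <- 1L
  if (ncol(d) >= 2L && tolower(colnames(d)[1L]) %in% c("fid") &&
      tolower(colnames(d)[2L]) %in% c("iid")) idc <- 2L
  rownames(d) <- as.character(d[[idc]])
  d[, -seq_len(idc), drop = FALSE]
}

## Exact Hardy-Weinberg test (two-sided, sum of probabilities <= observed),
## computed with the standard heterozygote-count recurrence.
.hwe_exact_p <- function(n_hom_min, n_het, n_hom_maj) {
  n <- n_hom_min + n_het + n_hom_maj
  if (n == 0L) return(NA_real_)
  nr <- 2L * n_hom_min + n_het        # rare allele count
  if (nr > n) return(.hwe_exact_p(n_hom_maj, n_het, n_hom_min))
  if (nr == 0L) return(1)
  hets <- seq.int(nr %% 2L, nr, by = 2L)
  lp <- vapply(hets, function(h) {
    a <- (nr - h) / 2
    b <- n - a - h
    h * log(2) + lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) -
      lgamma(b + 1) - (lgamma(2 * n + 1) - lgamma(nr + 1) -
                       lgamma(2 * n - nr + 1))
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Variant quality-control filter
#'
#' Drops SNPs failing minor-allele-frequency, missingness, or exact
#' Hardy-Weinberg-equilibrium thresholds.
#'
#' @param acc a `"plink_accessor"` or a dosage matrix.
#' @param min_maf minimum minor allele frequency (exclusive).
#' @param max_missing maximum missingness rate (exclusive).
#' @param hwe_p minimum exact HWE p-value (exclusive).
#' @return list with `keep` (indices of passing SNPs) and `report`
#'   (per-criterion failure counts).
#' @export
qc_filter <- function(acc, min_maf = 0.05, max_missing = 0.05,
                      hwe_p = 1e-5) {
  m <- if (inherits(acc, "plink_accessor")) acc$m else ncol(acc)
  maf <- miss <- hwe <- numeric(m)
  for (j in seq_len(m)) {
    g <- if (inherits(acc, "plink_accessor")) get_dosages(acc, j)[, 1L]
         else acc[, j]
    miss[j] <- mean(is.na(g))
    g <- g[!is.na(g)]
    p <- if (length(g)) mean(g) / 2 else 0
    maf[j] <- min(p, 1 - p)
    hwe[j] <- if (length(g))
      .hwe_exact_p(sum(g == 2), sum(g == 1), sum(g == 0)) else NA_real_
  }
  pass_maf <- maf > min_maf
  pass_miss <- miss < max_missing
  pass_hwe <- !is.na(hwe) & hwe > hwe_p
  keep <- which(pass_maf & pass_miss & pass_hwe)
  list(keep = keep, maf = maf,
       report = c(n_snps = m, fail_maf = sum(!pass_maf),
                  fail_missing = sum(!pass_miss),
                  fail_hwe = sum(!pass_hwe), kept = length(keep)))
}
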