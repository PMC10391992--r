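#' Genotype dosage container
#'
#' Bundles a samples-by-SNPs dosage matrix (alternative-allele dose in
#' \[0, 2\], `NA` allowed) with per-SNP metadata and per-sample cohort
#' assignment. Positions are 1-based; MAF is the folded (minor) allele
#' frequency.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns, with
#'   dimnames set to sample and SNP ids.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf` (one row per dosage column, same order).
#' @param samples Tibble with columns `sample_id`, `cohort` (one row per
#'   dosage row, same order).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, snps, samples) {
  stopifnot(is.matrix(dosages),
            nrow(snps) == ncol(dosages),
            nrow(samples) == nrow(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("dosages must lie in [0, 2] (or be NA)")
  }
  if (anyDuplicated(snps$snp_id)) abort("snp ids must be unique")
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique")
  if (any(snps$pos <= 0)) abort("SNP positions must be positive (1-based)")
  dimnames(dosages) <- list(samples$sample_id, snps$snp_id)
  structure(list(dosages = dosages, snps = as_tibble(snps),
                 samples = as_tibble(samples)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs, %d cohort(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              dplyr::n_distinct(x$samples$cohort)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Methylation matrix container
#'
#' Samples-by-CpGs methylation values plus CpG positions and a processing
#' stage tag. At the `"raw"` stage values are Illumina-style beta-values in
#' \[0, 1\]; after `inverse_normal_transform()` (`"INT"`) or
#' `adjust_methylation()` (`"residual"`) they are unbounded.
#'
#' @param values Numeric matrix, samples in rows, CpGs in columns.
#' @param cpgs Tibble with columns `cpg_id`, `chrom`, `pos`.
#' @param samples Tibble with columns `sample_id`, `cohort`.
#' @param stage One of `"raw"`, `"INT"`, `"residual"`.
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(values, cpgs, samples,
                        stage = c("raw", "INT", "residual")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values),
            nrow(cpgs) == ncol(values),
            nrow(samples) == nrow(values))
  if (anyDuplicated(cpgs$cpg_id)) abort("cpg ids must be unique")
  if (stage == "raw") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) abort("raw beta-values must lie in [0, 1]")
  }
  dimnames(values) <- list(samples$sample_id, cpgs$cpg_id)
  structure(list(values = values, cpgs = as_tibble(cpgs),
                 samples = as_tibble(samples), stage = stage),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d samples x %d CpGs [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

# subset helpers used throughout the pipeline ------------------------------

subset_geno_samples <- function(geno, keep) {
  geno_matrix(geno$dosages[keep, , drop = FALSE], geno$snps,
              geno$samples[keep, , drop = FALSE])
}

subset_geno_snps <- function(geno, keep) {
  geno_matrix(geno$dosages[, keep, drop = FALSE],
              geno$snps[keep, , drop = FALSE], geno$samples)
}

subset_meth <- function(meth, keep_samples = NULL, keep_cpgs = NULL) {
  v <- meth$values
  s <- meth$samples
  p <- meth$cpgs
  if (!is.null(keep_samples)) {
    v <- v[keep_samples, , drop = FALSE]
    s <- s[keep_samples, , drop = FALSE]
  }
  if (!is.null(keep_cpgs)) {
    v <- v[, keep_cpgs, drop = FALSE]
    p <- p[keep_cpgs, , drop = FALSE]
  }
  structure(list(values = v, cpgs = as_tibble(p), samples = as_tibble(s),
                 stage = meth$stage),
            class = "meth_matrix")
}
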