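#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternative homozygote).
#' @return Exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("at least one genotype must be observed")
  n_alt <- n_Aa + 2L * n_aa
  n_minor <- min(n_alt, 2L * n - n_alt)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | n, n_minor) up to a constant
  n_hom_min <- (n_minor - hets) / 2
  n_hom_maj <- n - hets - n_hom_min
  logp <- hets * log(2) - lfactorial(n_hom_min) - lfactorial(hets) -
    lfactorial(n_hom_maj)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) abort("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-7)]))
}

#' Genotype QC: MAF, Hardy-Weinberg and missingness filters
#'
#' Removes samples with missingness above `sample_miss_max` first, then
#' recomputes per-SNP statistics and removes SNPs with folded MAF strictly
#' below `maf_min`, exact Hardy-Weinberg p strictly below `hwe_p_min`
#' (computed on hard-called dosages), or missingness above `snp_miss_max`.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min,hwe_p_min,snp_miss_max,sample_miss_max Thresholds.
#' @return List: `geno` (filtered) and `report` (tibble `reason`, `n`).
#' @export
filter_genotypes <- function(geno, maf_min = 0.01, hwe_p_min = 1e-6,
                             snp_miss_max = 0.03, sample_miss_max = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (nrow(geno$dosages) == 0 || ncol(geno$dosages) == 0) {
    abort("empty genotype matrix")
  }
  d <- geno$dosages
  samp_miss <- rowMeans(is.na(d))
  drop_samp <- samp_miss > sample_miss_max
  geno <- subset_geno_samples(geno, !drop_samp)
  d <- geno$dosages

  snp_miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(d)
  hwe_p <- vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(1)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))

  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  fail_miss <- snp_miss > snp_miss_max
  keep <- !(fail_maf | fail_hwe | fail_miss)
  if (!any(keep)) abort("all SNPs removed by QC filters")
  report <- tibble(
    reason = c("sample_missingness", "snp_maf", "snp_hwe", "snp_missingness"),
    n = c(sum(drop_samp), sum(fail_maf), sum(fail_hwe), sum(fail_miss)))
  out <- subset_geno_snps(geno, keep)
  out$snps$maf <- maf[keep]
  list(geno = out, report = report)
}

#' Probe QC: missingness and mask-list filters for methylation
#'
#' @param meth A raw-stage [meth_matrix()].
#' @param probe_miss_max Remove probes with missingness strictly above this.
#' @param sample_miss_max Remove samples with missingness strictly above this.
#' @param mask_list Optional character vector of probe ids to drop (e.g.
#'   SNP-in-probe or cross-hybridising masks supplied externally).
#' @return List: `meth` (filtered) and `report` (tibble `reason`, `n`).
#' @export
filter_probes <- function(meth, probe_miss_max = 0.05,
                          sample_miss_max = 0.05, mask_list = NULL) {
  stopifnot(inherits(meth, "meth_matrix"))
  if (meth$stage != "raw") abort("filter_probes expects raw-stage methylation")
  v <- meth$values
  samp_miss <- rowMeans(is.na(v))
  drop_samp <- samp_miss > sample_miss_max
  meth <- subset_meth(meth, keep_samples = !drop_samp)
  v <- meth$values
  probe_miss <- colMeans(is.na(v))
  fail_miss <- probe_miss > probe_miss_max
  fail_mask <- meth$cpgs$cpg_id %in% (mask_list %||% character(0))
  keep <- !(fail_miss | fail_mask)
  if (!any(keep)) abort("all probes removed by QC filters")
  report <- tibble(
    reason = c("sample_missingness", "probe_missingness", "probe_masked"),
    n = c(sum(drop_samp), sum(fail_miss), sum(fail_mask)))
  list(meth = subset_meth(meth, keep_cpgs = keep), report = report)
}

#' Rank-based inverse normal transformation (Blom offset)
#'
#' Maps values to normal quantiles through their ranks:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties and
#' missing values preserved. `n` counts non-missing values.
#'
#' @param values Numeric vector (>= 3 non-missing, non-constant).
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) abort("need at least 3 non-missing values")
  x <- values[ok]
  if (max(x) == min(x)) abort("constant vector: ranks are undefined")
  r <- rank(x, ties.method = "average")
  c_off <- 3 / 8
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - c_off) / (n - 2 * c_off + 1))
  out
}

#' Inverse-normal transform every CpG of a methylation matrix
#'
#' @param meth A raw-stage [meth_matrix()].
#' @return An INT-stage [meth_matrix()].
#' @export
int_transform <- function(meth) {
  stopifnot(inherits(meth, "meth_matrix"))
  v <- apply(meth$values, 2, inverse_normal_transform)
  meth_matrix(v, meth$cpgs, meth$samples, stage = "INT")
}

# one-way random-intercept shrinkage of level means, method of moments
shrink_random_factor <- function(y, f) {
  f <- droplevels(factor(f))
  k <- nlevels(f)
  if (k < 2) return(y)
  means <- tapply(y, f, mean)
  ns <- tabulate(f)
  resid_within <- y - means[as.integer(f)]
  n <- length(y)
  sigma2 <- sum(resid_within^2) / max(1, n - k)
  # between-group mean square -> variance component (unbalanced MoM)
  gm <- mean(y)
  ssb <- sum(ns * (means - gm)^2)
  n0 <- (n - sum(ns^2) / n) / (k - 1)
  tau2 <- max(0, (ssb / (k - 1) - sigma2) / n0)
  shrink <- tau2 / (tau2 + sigma2 / ns)  # BLUP factor per level
  y - (shrink * (means - gm))[as.integer(f)]
}

#' Residualise methylation on covariates
#'
#' Per CpG, removes fixed-effect covariates and grouping-factor effects from
#' INT-transformed methylation. Grouping factors are treated as categorical
#' fixed effects by default (one-hot, reference level dropped); setting
#' `grouping_mode = "random"` instead fits a single random intercept per
#' factor by method-of-moments and subtracts shrunken level means.
#'
#' @param meth An INT-stage [meth_matrix()].
#' @param covars Covariate tibble with a `sample_id` column matching the
#'   methylation samples.
#' @param fixed Character vector of fixed-effect covariate names (numeric or
#'   categorical columns of `covars`).
#' @param grouping Character vector of grouping-factor names (e.g. plate,
#'   chip position, family id).
#' @param grouping_mode `"fixed"` (default) or `"random"`.
#' @return A residual-stage [meth_matrix()].
#' @export
adjust_methylation <- function(meth, covars, fixed = character(),
                               grouping = character(),
                               grouping_mode = c("fixed", "random")) {
  stopifnot(inherits(meth, "meth_matrix"))
  grouping_mode <- match.arg(grouping_mode)
  if (meth$stage == "raw") {
    warn("adjusting raw-stage methylation; INT is usually applied first")
  }
  idx <- match(meth$samples$sample_id, covars$sample_id)
  if (anyNA(idx)) abort("covariates missing for some methylation samples")
  cv <- covars[idx, , drop = FALSE]
  for (f in fixed) {
    if (anyNA(cv[[f]])) abort(sprintf("fixed covariate '%s' has missing values", f))
  }
  terms <- fixed
  if (grouping_mode == "fixed") terms <- c(terms, grouping)
  if (length(terms)) {
    df <- as.data.frame(cv[, terms, drop = FALSE])
    for (nm in names(df)) {
      if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
        df[[nm]] <- factor(df[[nm]])
      }
    }
    X <- stats::model.matrix(~ ., data = df)
  } else {
    X <- matrix(1, nrow(meth$values), 1)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warn(sprintf("design is rank-deficient; dropping %d aliased column(s)",
                 ncol(X) - qr_x$rank))
  }
  res <- qr.resid(qr_x, meth$values)
  if (grouping_mode == "random" && length(grouping)) {
    for (gf in grouping) {
      res <- apply(res, 2, shrink_random_factor, f = cv[[gf]])
    }
  }
  res <- unname(res)
  dimnames(res) <- list(meth$samples$sample_id, meth$cpgs$cpg_id)
  structure(list(values = res, cpgs = meth$cpgs, samples = meth$samples,
                 stage = "residual"),
            class = "meth_matrix")
}
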