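#' Classify SNP-CpG pairs as cis or trans
#'
#' A pair is cis iff SNP and CpG are on the same chromosome and separated by
#' no more than `window` base pairs (inclusive); everything else, including
#' all cross-chromosome pairs, is trans.
#'
#' @param snp_chrom,snp_pos,cpg_chrom,cpg_pos Vectors of positions (1-based).
#' @param window Distance cutoff in bp (default 1 Mbp).
#' @return Character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, cpg_chrom, cpg_pos,
                               window = 1e6) {
  if (any(c(snp_pos, cpg_pos) <= 0)) abort("positions must be positive")
  ifelse(as.character(snp_chrom) == as.character(cpg_chrom) &
           abs(snp_pos - cpg_pos) <= window, "cis", "trans")
}

# slope/SE/p for every SNP x CpG pair by closed-form simple regression on
# centred matrices; missing dosages mean-imputed per SNP beforehand
all_pairs_ols <- function(G, M) {
  n <- nrow(G)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sxx <- colSums(Gc^2)              # per SNP
  syy <- colSums(Mc^2)              # per CpG
  sxy <- crossprod(Gc, Mc)          # SNP x CpG
  beta <- sxy / sxx
  # residual SS = syy - beta * sxy, elementwise
  sse <- pmax(sweep(-beta * sxy, 2, syy, "+"), 0)
  df <- n - 2
  se <- sqrt(sweep(sse / df, 1, sxx, "/"))
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0] <- .Machine$double.xmin   # noiseless fits: underflow-safe floor
  list(beta = beta, se = se, p = p, n = n)
}

#' Per-cohort SNP x CpG association scan with candidate retention
#'
#' For every SNP-CpG pair, fits a simple linear regression of residualised
#' methylation on alternative-allele dosage and retains pairs meeting the
#' liberal type-specific candidate threshold (`p <= p_cis` for cis,
#' `p <= p_trans` for trans; both inclusive). Sporadically missing dosages
#' are mean-imputed per SNP within the cohort; zero-variance SNPs are
#' skipped and reported via the `skipped_snps` attribute. CpGs are processed
#' in blocks to bound memory; results do not depend on the block size.
#'
#' @param geno A [geno_matrix()] for one cohort.
#' @param meth A residual-stage [meth_matrix()] with the same samples.
#' @param p_cis,p_trans Candidate retention thresholds.
#' @param window cis window in bp.
#' @param cohort Cohort label recorded in the output (defaults to the
#'   genotype object's single cohort).
#' @param block_size CpGs per processing block.
#' @return Tibble of association records: `snp_id`, `cpg_id`, `cohort`,
#'   `type`, `beta`, `se`, `p`, `n`.
#' @export
scan_cohort <- function(geno, meth, p_cis = 5e-3, p_trans = 5e-6,
                        window = 1e6, cohort = NULL, block_size = 2000L) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(meth, "meth_matrix"))
  if (!identical(geno$samples$sample_id, meth$samples$sample_id)) {
    abort("genotype and methylation samples must be aligned")
  }
  if (meth$stage == "raw") {
    warn("scanning raw-stage methylation; residualised input is expected")
  }
  cohort <- cohort %||% unique(geno$samples$cohort)[1]
  G <- geno$dosages
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  poly <- matrixStats_colVars(G) > 0
  skipped <- geno$snps$snp_id[!poly]
  G <- G[, poly, drop = FALSE]
  snps <- geno$snps[poly, , drop = FALSE]
  if (ncol(G) == 0) abort("no polymorphic SNPs in cohort")

  n_cpg <- ncol(meth$values)
  blocks <- split(seq_len(n_cpg), ceiling(seq_len(n_cpg) / block_size))
  out <- purrr::map(blocks, function(cols) {
    M <- meth$values[, cols, drop = FALSE]
    fit <- all_pairs_ols(G, M)
    cpgs <- meth$cpgs[cols, , drop = FALSE]
    type <- outer(seq_len(nrow(snps)), seq_along(cols),
                  function(i, j) snps$chrom[i] == cpgs$chrom[j] &
                    abs(snps$pos[i] - cpgs$pos[j]) <= window)
    thr <- ifelse(type, p_cis, p_trans)
    keep <- which(fit$p <= thr, arr.ind = TRUE)
    if (nrow(keep) == 0) return(NULL)
    tibble(snp_id = snps$snp_id[keep[, 1]],
           cpg_id = cpgs$cpg_id[keep[, 2]],
           cohort = cohort,
           type = ifelse(type[keep], "cis", "trans"),
           beta = fit$beta[keep], se = fit$se[keep], p = fit$p[keep],
           n = fit$n)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(snp_id = character(), cpg_id = character(),
                  cohort = character(), type = character(), beta = numeric(),
                  se = numeric(), p = numeric(), n = integer())
  }
  attr(res, "skipped_snps") <- skipped
  res
}

# column variances without an extra dependency
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  (colSums(x^2) - colSums(x)^2 / n) / (n - 1)
}

#' Cell-proportion interaction scan (cell type-specific meQTLs)
#'
#' For cis SNP-CpG pairs, fits `methylation ~ G + prop + G:prop` where
#' `prop` is the per-sample proportion of the focal blood cell type, and
#' records the interaction term. The methylation input must have been
#' adjusted *without* the focal cell proportion as a covariate.
#'
#' @param geno A [geno_matrix()].
#' @param meth A residual-stage [meth_matrix()] (focal proportion excluded
#'   from its adjustment).
#' @param cell_prop Numeric vector of per-sample cell proportions, aligned
#'   with the samples.
#' @param p_keep Retention threshold on the interaction p-value (inclusive).
#' @param window cis window in bp.
#' @param cohort Cohort label.
#' @return Tibble of interaction records (`beta`, `se`, `p` refer to the
#'   interaction term; `n` is the sample count; df = n - 4).
#' @export
interaction_scan <- function(geno, meth, cell_prop, p_keep = 5e-3,
                             window = 1e6, cohort = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(meth, "meth_matrix"))
  if (length(cell_prop) != nrow(geno$dosages)) {
    abort("cell_prop must have one value per sample")
  }
  if (max(cell_prop) == min(cell_prop)) abort("cell proportion is constant")
  cohort <- cohort %||% unique(geno$samples$cohort)[1]
  n <- nrow(geno$dosages)
  G <- geno$dosages
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  recs <- list()
  for (i in seq_len(ncol(G))) {
    g <- G[, i]
    if (var(g) == 0) next
    cis_cols <- which(meth$cpgs$chrom == geno$snps$chrom[i] &
                        abs(meth$cpgs$pos - geno$snps$pos[i]) <= window)
    if (length(cis_cols) == 0) next
    X <- cbind(1, g, cell_prop, g * cell_prop)
    qr_x <- qr(X)
    if (qr_x$rank < 4) next
    Y <- meth$values[, cis_cols, drop = FALSE]
    cf <- qr.coef(qr_x, Y)
    res <- qr.resid(qr_x, Y)
    sigma2 <- colSums(res^2) / (n - 4)
    xtx_inv <- chol2inv(qr.R(qr_x))
    se_int <- sqrt(sigma2 * xtx_inv[4, 4])
    tstat <- cf[4, ] / se_int
    p <- 2 * pt(abs(tstat), n - 4, lower.tail = FALSE)
    keep <- which(p <= p_keep)
    if (length(keep)) {
      recs[[length(recs) + 1L]] <- tibble(
        snp_id = geno$snps$snp_id[i],
        cpg_id = meth$cpgs$cpg_id[cis_cols[keep]],
        cohort = cohort, type = "cis",
        beta = unname(cf[4, keep]), se = unname(se_int[keep]),
        p = unname(p[keep]), n = n)
    }
  }
  res <- bind_rows(recs)
  if (nrow(res) == 0) {
    res <- tibble(snp_id = character(), cpg_id = character(),
                  cohort = character(), type = character(), beta = numeric(),
                  se = numeric(), p = numeric(), n = integer())
  }
  res
}
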