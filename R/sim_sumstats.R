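#' Simulate exposure/outcome GWAS summary statistics under pleiotropy or linkage
#'
#' Generates marginal association statistics for a region of SNPs whose LD
#' follows an AR(1) correlation structure. Under `"pleiotropy"` a single
#' causal SNP drives both the exposure (methylation) and the outcome
#' (expression or trait): the marginal beta at SNP j is
#' `r(j, causal) * causal beta`, so every SNP's outcome/exposure ratio equals
#' the planted causal ratio. Under `"linkage"` two distinct causal SNPs in LD
#' drive exposure and outcome separately, so the ratio varies across SNPs —
#' the signature the HEIDI test is built to detect. Estimation noise is
#' multivariate normal with covariance `R / n` (the sampling covariance of
#' standardised marginal betas), independent between the two studies.
#'
#' @param scenario `"pleiotropy"` or `"linkage"`.
#' @param n_snps Number of SNPs in the region (>= 25 so HEIDI can pick
#'   alternative instruments).
#' @param ld_rho AR(1) LD correlation between adjacent SNPs.
#' @param causal_index Index of the (exposure) causal SNP.
#' @param causal2_index Index of the outcome causal SNP (linkage only).
#' @param b_exposure Causal effect of the exposure-causal SNP on the exposure.
#' @param b_ratio True exposure-to-outcome ratio effect (pleiotropy), or
#' @param b_outcome outcome-causal effect (linkage).
#' @param n_exposure,n_outcome Study sample sizes (SE = 1/sqrt(n)).
#' @param noise If `FALSE`, return noiseless marginal betas.
#' @param seed Integer seed.
#' @return List: `exposure` and `outcome` summary tibbles (`snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `freq`, `b`, `se`, `p`, `n`), `ld` (SNP correlation
#'   matrix, signed), and `truth` (scenario, causal indices, true ratio).
#' @export
simulate_summary_stats <- function(scenario = c("pleiotropy", "linkage"),
                                   n_snps = 30, ld_rho = 0.9,
                                   causal_index = 15, causal2_index = 17,
                                   b_exposure = 0.3, b_ratio = 0.5,
                                   b_outcome = 0.15,
                                   n_exposure = 2358, n_outcome = 31684,
                                   noise = TRUE, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_snps < 25) abort("region must have >= 25 SNPs for HEIDI selection")
  R <- ld_rho^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  r_c1 <- R[, causal_index]
  b_exp_true <- r_c1 * b_exposure
  if (scenario == "pleiotropy") {
    b_out_true <- r_c1 * b_exposure * b_ratio
    true_ratio <- b_ratio
  } else {
    r_c2 <- R[, causal2_index]
    b_out_true <- r_c2 * b_outcome
    true_ratio <- NA_real_  # no single ratio exists under linkage
  }
  se_exp <- rep(1 / sqrt(n_exposure), n_snps)
  se_out <- rep(1 / sqrt(n_outcome), n_snps)
  withr::with_seed(as.integer(seed), {
    if (noise) {
      L <- chol(R + diag(1e-10, n_snps))
      b_exp <- b_exp_true + drop(crossprod(L, rnorm(n_snps))) / sqrt(n_exposure)
      b_out <- b_out_true + drop(crossprod(L, rnorm(n_snps))) / sqrt(n_outcome)
    } else {
      b_exp <- b_exp_true
      b_out <- b_out_true
    }
  })
  mk <- function(b, se, n) {
    tibble(snp_id = sprintf("rs%04d", seq_len(n_snps)),
           chrom = "1", pos = 1000000L + seq_len(n_snps) * 5000L,
           a1 = "A", a2 = "G", freq = 0.3,
           b = b, se = se,
           p = 2 * pnorm(-abs(b / se)), n = n)
  }
  ids <- sprintf("rs%04d", seq_len(n_snps))
  dimnames(R) <- list(ids, ids)
  list(exposure = mk(b_exp, se_exp, n_exposure),
       outcome = mk(b_out, se_out, n_outcome),
       ld = R,
       truth = list(scenario = scenario, causal_index = causal_index,
                    causal2_index = if (scenario == "linkage") causal2_index
                                    else NA_integer_,
                    true_ratio = true_ratio))
}
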