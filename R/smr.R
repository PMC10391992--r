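#' Harmonise exposure and outcome summary statistics
#'
#' Joins the two tables on SNP id, flips outcome betas (and allele
#' frequencies) where the effect/other alleles are swapped, drops
#' strand-ambiguous (A/T, C/G) SNPs, and drops SNPs whose aligned allele
#' frequencies differ by more than `freq_max_diff`.
#'
#' @param exposure,outcome Summary-statistic tibbles with columns `snp_id`,
#'   `a1`, `a2`, `freq`, `b`, `se`, `p` (and optionally `n`).
#' @param freq_max_diff Allele-frequency mismatch tolerance after alignment.
#' @return List: `aligned` (tibble with exposure columns suffixed `_zx` and
#'   outcome columns `_zy`), `n_dropped_ambiguous`, `n_dropped_freq`,
#'   `n_dropped_mismatch`.
#' @export
harmonize <- function(exposure, outcome, freq_max_diff = 0.2) {
  j <- inner_join(exposure, outcome, by = "snp_id",
                  suffix = c("_zx", "_zy"))
  if (nrow(j) == 0) abort("no shared SNPs between exposure and outcome")
  base <- function(x) toupper(x)
  ambiguous <- paste0(base(j$a1_zx), base(j$a2_zx)) %in%
    c("AT", "TA", "CG", "GC")
  n_amb <- sum(ambiguous)
  j <- j[!ambiguous, , drop = FALSE]
  same <- base(j$a1_zy) == base(j$a1_zx) & base(j$a2_zy) == base(j$a2_zx)
  swapped <- base(j$a1_zy) == base(j$a2_zx) & base(j$a2_zy) == base(j$a1_zx)
  n_mis <- sum(!(same | swapped))
  j <- j[same | swapped, , drop = FALSE]
  flip <- base(j$a1_zy) == base(j$a2_zx)
  j$b_zy[flip] <- -j$b_zy[flip]
  j$freq_zy[flip] <- 1 - j$freq_zy[flip]
  bad_freq <- abs(j$freq_zx - j$freq_zy) > freq_max_diff
  n_freq <- sum(bad_freq)
  j <- j[!bad_freq, , drop = FALSE]
  j$a1 <- j$a1_zx
  j$a2 <- j$a2_zx
  list(aligned = as_tibble(j), n_dropped_ambiguous = n_amb,
       n_dropped_freq = n_freq, n_dropped_mismatch = n_mis)
}

#' Summary-based Mendelian randomisation (2SLS ratio) test
#'
#' The instrument is the exposure's most significant SNP; the causal-effect
#' estimate is the Wald ratio `b_xy = b_zy / b_zx` with first-order delta
#' variance `var = (b_zy^2/b_zx^2) (se_zy^2/b_zy^2 + se_zx^2/b_zx^2)`;
#' `T = b_xy^2 / var` is referred to a one-degree chi-square.
#'
#' @param b_zx,se_zx Instrument effect on the exposure and its SE.
#' @param b_zy,se_zy Instrument effect on the outcome and its SE.
#' @return Tibble: `b_smr`, `se_smr`, `p_smr` (vectorised).
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy) {
  if (any(b_zx == 0)) abort("instrument effect on exposure must be nonzero")
  if (any(b_zy == 0 & se_zy == 0)) {
    abort("degenerate outcome statistics (b_zy = 0 with se_zy = 0)")
  }
  b_xy <- b_zy / b_zx
  v <- (b_zy^2 / b_zx^2) * (se_zy^2 / b_zy^2 + se_zx^2 / b_zx^2)
  # b_zy = 0 with se_zy > 0: ratio 0, variance from the delta method limit
  zero <- b_zy == 0
  v[zero] <- (se_zy[zero]^2) / (b_zx[zero]^2)
  t_stat <- b_xy^2 / v
  tibble(b_smr = b_xy, se_smr = sqrt(v),
         p_smr = pchisq(t_stat, df = 1, lower.tail = FALSE))
}

#' Select alternative instruments for the HEIDI test
#'
#' Eligible SNPs have exposure p-value at or below `p_inst_max` and LD with
#' the top instrument strictly between `r2_low` and `r2_high`; they are
#' ranked by exposure significance and truncated at `max_snps` (up to
#' twenty alternative SNPs by default).
#'
#' @param stats Tibble with `snp_id` and exposure p-values `p_zx`.
#' @param top_snp Id of the top instrument.
#' @param ld Square r-squared matrix covering the region.
#' @param r2_low,r2_high LD eligibility window (exclusive bounds).
#' @param max_snps Cap on the number of alternative SNPs.
#' @param p_inst_max Relaxed instrument p-value threshold.
#' @return Character vector of SNP ids (empty, with attribute `reason`, when
#'   fewer than 3 SNPs qualify).
#' @export
select_heidi_snps <- function(stats, top_snp, ld, r2_low = 0.05,
                              r2_high = 0.9, max_snps = 20,
                              p_inst_max = 1.57e-3) {
  if (!top_snp %in% rownames(ld)) abort("LD matrix does not cover top SNP")
  r2 <- ld[stats$snp_id, top_snp]
  elig <- stats$snp_id != top_snp & stats$p_zx <= p_inst_max &
    r2 > r2_low & r2 < r2_high
  ids <- stats$snp_id[elig][order(stats$p_zx[elig])]
  ids <- head(ids, max_snps)
  if (length(ids) < 3) {
    out <- character(0)
    attr(out, "reason") <- sprintf(
      "only %d eligible alternative SNPs (need >= 3)", length(ids))
    return(out)
  }
  ids
}

#' HEIDI test of heterogeneity in dependent instruments
#'
#' Computes, for each alternative SNP i, the difference
#' `d_i = b_xy(i) - b_xy(top)` between its Wald ratio and the top
#' instrument's, with the covariance of the `d_i` from the first-order delta
#' method using `cov(b(i), b(j)) = r_ij se_i se_j` within each study (LD r
#' signed). The standardised differences `z_i` give `T = sum z_i^2`, whose
#' null distribution is approximated by a Satterthwaite moment-matched
#' scaled chi-square using the eigenvalues of the correlation matrix of the
#' `d_i`. A small p-value is evidence that different causal variants in LD
#' (linkage), rather than one shared variant, drive the two traits.
#'
#' @param aligned Harmonised tibble covering the top and alternative SNPs
#'   (`snp_id`, `b_zx`, `se_zx`, `b_zy`, `se_zy`).
#' @param top_snp Top instrument id.
#' @param alt_snps Alternative instrument ids (from [select_heidi_snps()]).
#' @param ld Signed LD correlation matrix covering all the SNPs.
#' @return List: `p_heidi`, `n_snp`, `T`.
#' @export
heidi_test <- function(aligned, top_snp, alt_snps, ld) {
  if (length(alt_snps) < 3) abort("need at least 3 alternative SNPs")
  ids <- c(top_snp, alt_snps)
  ix <- match(ids, aligned$snp_id)
  if (anyNA(ix)) abort("aligned stats do not cover all HEIDI SNPs")
  bx <- aligned$b_zx[ix]; sx <- aligned$se_zx[ix]
  by <- aligned$b_zy[ix]; sy <- aligned$se_zy[ix]
  m <- length(ids)
  R <- ld[ids, ids]
  # joint covariance of (b_zx_1..m, b_zy_1..m); studies independent
  Cx <- R * tcrossprod(sx)
  Cy <- R * tcrossprod(sy)
  # Jacobian of d = (b_xy(i) - b_xy(top))_{i=2..m} wrt (b_zx, b_zy)
  J <- matrix(0, m - 1, 2 * m)
  for (i in 2:m) {
    r <- i - 1
    J[r, i] <- -by[i] / bx[i]^2        # d wrt b_zx(i)
    J[r, 1] <- by[1] / bx[1]^2         # d wrt b_zx(top)
    J[r, m + i] <- 1 / bx[i]           # d wrt b_zy(i)
    J[r, m + 1] <- -1 / bx[1]          # d wrt b_zy(top)
  }
  C <- rbind(cbind(Cx, matrix(0, m, m)), cbind(matrix(0, m, m), Cy))
  V <- J %*% C %*% t(J)
  dvec <- by[-1] / bx[-1] - by[1] / bx[1]
  dv <- diag(V)
  if (any(dv <= 0)) abort("non-positive variance in HEIDI covariance")
  z <- dvec / sqrt(dv)
  Rd <- V / tcrossprod(sqrt(dv))
  ev <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    # nearest-PD repair: shift eigenvalues up, keeping the trace scale
    shift <- -min(ev) + 1e-8
    inform(sprintf("HEIDI correlation repaired by eigenvalue shift %.2e",
                   shift))
    ev <- ev + shift
  }
  ev <- pmax(ev, 0)
  T_stat <- sum(z^2)
  scale <- sum(ev^2) / sum(ev)
  df <- sum(ev)^2 / sum(ev^2)
  list(p_heidi = pchisq(T_stat / scale, df, lower.tail = FALSE),
       n_snp = length(alt_snps), T = T_stat)
}

#' Run an SMR + HEIDI co-localisation design over exposure-outcome pairs
#'
#' For each exposure-outcome pair: harmonises the two summary tables (or
#' uses them as given when allele columns agree), takes the exposure's most
#' significant SNP as the instrument (ties by |b|/se then position), applies
#' [smr_test()] and [heidi_test()], and flags co-localisation when
#' `p_smr <= bonferroni_threshold(alpha, n_tests)` and `p_heidi > 0.05`.
#' Designs follow the three eQTL analyses plus the GWAS analysis:
#' `"cis_eqtl"`, `"trans_eqtl"`, `"targeted_trans"` (only SNP-CpG pairs more
#' than 5 Mbp apart are tested) and `"gwas"` (Bonferroni denominator =
#' number of CpGs x number of phenotype classes).
#'
#' @param design One of `"cis_eqtl"`, `"trans_eqtl"`, `"targeted_trans"`,
#'   `"gwas"`.
#' @param pairs Tibble of exposure-outcome pairs: `exposure_id`,
#'   `outcome_id`, and for `targeted_trans` a `distance` column (bp between
#'   instrument SNP and CpG).
#' @param exposure_stats Tibble: `exposure_id`, `snp_id`, `a1`, `a2`,
#'   `freq`, `b`, `se`, `p` (meQTL summary statistics per CpG).
#' @param outcome_stats Tibble: `outcome_id`, `snp_id`, `a1`, `a2`, `freq`,
#'   `b`, `se`, `p` (eQTL or GWAS summary statistics).
#' @param ld Signed LD correlation matrix covering the SNPs.
#' @param alpha Family-wise level for the Bonferroni cut.
#' @param n_classes Number of phenotype classes (gwas design).
#' @param heidi Logical: run the HEIDI filter.
#' @return Tibble of class `smr_result`: per pair `exposure_id`,
#'   `outcome_id`, `top_snp`, `b_smr`, `se_smr`, `p_smr`, `p_heidi`,
#'   `n_snp_heidi`, `significant`; attribute `p_threshold`.
#' @export
run_coloc <- function(design = c("cis_eqtl", "trans_eqtl", "targeted_trans",
                                 "gwas"),
                      pairs, exposure_stats, outcome_stats, ld,
                      alpha = 0.05, n_classes = NULL, heidi = TRUE) {
  design <- match.arg(design)
  if (design == "targeted_trans") {
    if (!"distance" %in% names(pairs)) {
      abort("targeted_trans design needs a distance column")
    }
    pairs <- filter(pairs, .data$distance > 5e6)
  }
  n_tests <- if (design == "gwas") {
    if (is.null(n_classes)) abort("gwas design needs n_classes")
    dplyr::n_distinct(pairs$exposure_id) * n_classes
  } else {
    nrow(pairs)
  }
  if (n_tests == 0) abort("no testable pairs under this design")
  thr <- bonferroni_threshold(alpha, n_tests)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ex <- filter(exposure_stats, .data$exposure_id == pairs$exposure_id[i])
    ou <- filter(outcome_stats, .data$outcome_id == pairs$outcome_id[i])
    h <- harmonize(ex, ou)
    al <- h$aligned
    al <- rename(al, p_zx = "p_zx", p_zy = "p_zy")
    ord <- order(al$p_zx, -abs(al$b_zx / al$se_zx),
                 if ("pos_zx" %in% names(al)) al$pos_zx else seq_len(nrow(al)))
    top <- al$snp_id[ord[1]]
    ti <- ord[1]
    sm <- smr_test(al$b_zx[ti], al$se_zx[ti], al$b_zy[ti], al$se_zy[ti])
    p_heidi <- NA_real_; n_snp <- NA_integer_
    if (heidi) {
      sel <- select_heidi_snps(
        tibble(snp_id = al$snp_id, p_zx = al$p_zx), top, ld^2)
      if (length(sel) >= 3) {
        ht <- heidi_test(al, top, sel, ld)
        p_heidi <- ht$p_heidi
        n_snp <- ht$n_snp
      }
    }
    tibble(exposure_id = pairs$exposure_id[i],
           outcome_id = pairs$outcome_id[i],
           top_snp = top, b_smr = sm$b_smr, se_smr = sm$se_smr,
           p_smr = sm$p_smr, p_heidi = p_heidi, n_snp_heidi = n_snp)
  })
  res$significant <- res$p_smr <= thr &
    (!heidi | (!is.na(res$p_heidi) & res$p_heidi > 0.05))
  attr(res, "p_threshold") <- thr
  attr(res, "design") <- design
  class(res) <- c("smr_result", class(res))
  res
}
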