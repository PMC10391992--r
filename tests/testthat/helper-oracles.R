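# Independent brute-force oracles, kept free of the package's own code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hardy-Weinberg exact p by direct enumeration of genotype configurations
# with the observed allele counts, probabilities from the multinomial
# conditional formula.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_alt <- n_Aa + 2 * n_aa
  hets <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  # P(h | n, n_alt) proportional to n! / (nAA! h! naa!) * 2^h
  logp <- sapply(hets, function(h) {
    naa <- (n_alt - h) / 2
    nAA <- n - h - naa
    lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
      h * log(2)
  })
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# DerSimonian-Laird meta-analysis, straight transcription of the formulas
oracle_dl <- function(beta, se) {
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bf)^2)
  k <- length(beta)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
          else 0
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * beta) / sum(ws)
  s <- sqrt(1 / sum(ws))
  list(beta = b, se = s, tau2 = tau2, p = 2 * pnorm(-abs(b / s)))
}

# naive re-application of the clumping rule, written independently
oracle_clump <- function(snp_stats, ld, r2_min, window) {
  df <- snp_stats[order(-snp_stats$n_cpgs, snp_stats$best_p,
                        snp_stats$pos), ]
  assigned <- rep(NA_character_, nrow(df))
  reps <- character(0)
  while (any(is.na(assigned))) {
    i <- which(is.na(assigned))[1]
    rep_id <- df$snp_id[i]
    reps <- c(reps, rep_id)
    assigned[i] <- rep_id
    for (j in which(is.na(assigned))) {
      if (df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window &&
          ld[df$snp_id[j], df$snp_id[i]] > r2_min) {
        assigned[j] <- rep_id
      }
    }
  }
  tibble::tibble(snp_id = df$snp_id, rep_snp_id = assigned)
}

# Monte-Carlo oracle for adjacent-SNP dosage correlation under the
# latent-Gaussian AR(1) threshold scheme
oracle_adjacent_dosage_cor <- function(rho, maf1, maf2, n_hap = 200000,
                                       seed = 99) {
  set.seed(seed)
  z1 <- rnorm(n_hap)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_hap)
  a1 <- as.numeric(z1 < qnorm(maf1))
  a2 <- as.numeric(z2 < qnorm(maf2))
  # dosage = sum of two independent haplotypes
  half <- n_hap / 2
  d1 <- a1[1:half] + a1[(half + 1):n_hap]
  d2 <- a2[1:half] + a2[(half + 1):n_hap]
  cor(d1, d2)
}

# small simulated cohort bundle reused across scan/meta tests
make_tiny_cohorts <- function(seed = 7, n_cohorts = 3, n = 120,
                              n_cis = 12, effect_r2 = 0.2,
                              n_mz = 15, n_dz = 15) {
  cfg <- sim_config(n_cohorts = n_cohorts,
                    samples_per_cohort = n, n_snps = 60, n_cpgs = 80,
                    ld_block_size = 5, ld_rho = 0.6,
                    n_cis_effects = n_cis, n_trans_effects = 0,
                    effect_r2 = effect_r2, n_mz_pairs = n_mz,
                    n_dz_pairs = n_dz, seed = seed)
  g <- simulate_genotypes(cfg)
  cp <- simulate_cpg_positions(cfg)
  tr <- plant_effects(g$geno, cp, cfg)
  mm <- simulate_methylation(g$geno, tr, g$pedigree, cfg, cp)
  cohorts <- list()
  peds <- list()
  for (co in unique(g$pedigree$cohort)) {
    rows <- g$pedigree$cohort == co
    geno_c <- meqtlmap:::subset_geno_samples(g$geno, rows)
    meth_c <- meqtlmap:::subset_meth(mm$meth, keep_samples = rows)
    meth_res <- adjust_methylation(
      int_transform(meth_c), mm$covars[rows, ],
      fixed = c("sex", "age", "smoking", "cd4t", "mono"),
      grouping = "plate")
    cohorts[[co]] <- list(geno = geno_c, meth = meth_res)
    peds[[co]] <- g$pedigree[rows, ]
  }
  list(config = cfg, geno = g$geno, pedigree = g$pedigree, truth = tr,
       cohorts = cohorts, pedigrees = peds, cpgs = cp, covars = mm$covars,
       meth = mm$meth)
}
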