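test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(ld_block_size = 1000, n_snps = 50), "block")
  expect_error(sim_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ace_params = c(0.5, 0.5, 0.5)), "ace_params")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(samples_per_cohort = 100, n_mz_pairs = 40,
                          n_dz_pairs = 40), "twin")
})

test_that("genotypes respect dosage range, MAF window and twin structure", {
  cfg <- sim_config(n_cohorts = 2, samples_per_cohort = c(700, 100),
                    n_snps = 80, ld_block_size = 8, ld_rho = 0.5,
                    n_mz_pairs = 150, n_dz_pairs = 150,
                    maf_range = c(0.1, 0.4), seed = 11)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$geno$dosages %in% 0:2))
  # realised MAF within the sampling window around the target range
  n2 <- 2 * nrow(g$geno$dosages)
  slack <- 3 * sqrt(0.25 / n2)
  expect_true(all(g$geno$snps$maf >= 0.1 - slack - 1e-9))
  expect_true(all(g$geno$snps$maf <= 0.4 + slack + 0.5 / n2))

  ped <- g$pedigree
  mz_fams <- unique(ped$family_id[ped$zygosity == "MZ"])
  for (fm in mz_fams[1:20]) {
    rows <- which(ped$family_id == fm)
    expect_identical(g$geno$dosages[rows[1], ], g$geno$dosages[rows[2], ])
  }
  # DZ twins share half their alleles on average: cross-twin dosage
  # correlation approximately 0.5
  dz_fams <- unique(ped$family_id[ped$zygosity == "DZ"])
  pair_rows <- t(vapply(dz_fams, function(fm) which(ped$family_id == fm),
                        integer(2)))
  d1 <- g$geno$dosages[pair_rows[, 1], ]
  d2 <- g$geno$dosages[pair_rows[, 2], ]
  rr <- vapply(seq_len(ncol(d1)),
               function(j) suppressWarnings(cor(d1[, j], d2[, j])),
               numeric(1))
  expect_lt(abs(mean(rr, na.rm = TRUE) - 0.5), 0.05)
})

test_that("ld_rho = 0 gives uncorrelated SNPs; AR(1) LD matches a Monte-Carlo oracle", {
  cfg0 <- sim_config(n_cohorts = 1, samples_per_cohort = 600, n_snps = 40,
                     ld_block_size = 5, ld_rho = 0, n_mz_pairs = 0,
                     n_dz_pairs = 0, seed = 5)
  g0 <- simulate_genotypes(cfg0)
  r <- cor(g0$geno$dosages)
  r2 <- r[upper.tri(r)]^2
  expect_lt(mean(r2), 3 / 600)

  # rho = 0.9, block 10: adjacent within-block dosage correlation vs the
  # brute-force threshold-scheme oracle
  cfg9 <- sim_config(n_cohorts = 1, samples_per_cohort = 2000, n_snps = 20,
                     ld_block_size = 10, ld_rho = 0.9, n_mz_pairs = 0,
                     n_dz_pairs = 0, maf_range = c(0.2, 0.3), seed = 1)
  g9 <- simulate_genotypes(cfg9)
  maf <- g9$geno$snps$maf
  # average over within-block adjacent pairs on chromosome 1
  obs <- vapply(1:9, function(j) {
    cor(g9$geno$dosages[, j], g9$geno$dosages[, j + 1])
  }, numeric(1))
  exp_mc <- vapply(1:9, function(j) {
    oracle_adjacent_dosage_cor(0.9, maf[j], maf[j + 1])
  }, numeric(1))
  expect_lt(abs(mean(obs) - mean(exp_mc)), 0.05)
})

test_that("plant_effects honours the cis window, caps and determinism", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 100, n_snps = 60,
                    n_cpgs = 60, ld_block_size = 5, n_mz_pairs = 0,
                    n_dz_pairs = 0, n_cis_effects = 10,
                    n_trans_effects = 5, seed = 3)
  g <- simulate_genotypes(cfg)
  cp <- simulate_cpg_positions(cfg)
  tr <- plant_effects(g$geno, cp, cfg)
  expect_equal(nrow(tr), 15)
  expect_false(any(duplicated(tr[, c("snp_id", "cpg_id")])))
  # labels agree with the classifier, zero mismatches
  si <- match(tr$snp_id, g$geno$snps$snp_id)
  ci <- match(tr$cpg_id, cp$cpg_id)
  expect_identical(
    classify_cis_trans(g$geno$snps$chrom[si], g$geno$snps$pos[si],
                       cp$chrom[ci], cp$pos[ci]),
    tr$type)
  cis <- tr[tr$type == "cis", ]
  expect_true(all(abs(g$geno$snps$pos[match(cis$snp_id, g$geno$snps$snp_id)] -
                        cp$pos[match(cis$cpg_id, cp$cpg_id)]) <= 1e6))
  expect_true(all(table(tr$cpg_id) <= cfg$max_effects_per_cpg))
  expect_identical(tr, plant_effects(g$geno, cp, cfg))

  cfg0 <- sim_config(n_cohorts = 1, samples_per_cohort = 100, n_snps = 60,
                     n_cpgs = 60, ld_block_size = 5, n_mz_pairs = 0,
                     n_dz_pairs = 0, n_cis_effects = 0, n_trans_effects = 0)
  expect_equal(nrow(plant_effects(g$geno, cp, cfg0)), 0)

  cfg_big <- sim_config(n_cohorts = 1, samples_per_cohort = 100,
                        n_snps = 60, n_cpgs = 60, ld_block_size = 5,
                        n_mz_pairs = 0, n_dz_pairs = 0,
                        n_cis_effects = 10000, n_trans_effects = 0,
                        max_effects_per_cpg = 1)
  expect_error(plant_effects(g$geno, cp, cfg_big), "insufficient")
})

test_that("methylation stays in (0,1) and cross-twin correlations match ACE", {
  # A = 0.6, C = 0.2 -> latent rMZ = 0.8, rDZ = 0.5
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 4000, n_snps = 20,
                    n_cpgs = 40, ld_block_size = 5,
                    ace_params = c(0.6, 0.2, 0.2),
                    n_mz_pairs = 1000, n_dz_pairs = 1000,
                    n_cis_effects = 0, n_trans_effects = 0,
                    cov_effect_sd = 0, batch_sd = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  cp <- simulate_cpg_positions(cfg)
  tr <- plant_effects(g$geno, cp, cfg)
  mm <- simulate_methylation(g$geno, tr, g$pedigree, cfg, cp)
  expect_true(all(mm$meth$values > 0 & mm$meth$values < 1))

  ped <- g$pedigree
  twin_cor <- function(zyg) {
    fams <- unique(ped$family_id[ped$zygosity == zyg])
    rows <- t(vapply(fams, function(fm) which(ped$family_id == fm),
                     integer(2)))
    mean(vapply(seq_len(ncol(mm$latent)), function(j) {
      cor(mm$latent[rows[, 1], j], mm$latent[rows[, 2], j])
    }, numeric(1)))
  }
  expect_lt(abs(twin_cor("MZ") - 0.8), 0.04)
  expect_lt(abs(twin_cor("DZ") - 0.5), 0.04)

  # A = 0: both cross-twin correlations collapse to C
  cfg0 <- sim_config(n_cohorts = 1, samples_per_cohort = 4000, n_snps = 20,
                     n_cpgs = 40, ld_block_size = 5,
                     ace_params = c(0, 0.3, 0.7),
                     n_mz_pairs = 1000, n_dz_pairs = 1000,
                     n_cis_effects = 0, n_trans_effects = 0,
                     cov_effect_sd = 0, batch_sd = 0, seed = 22)
  g0 <- simulate_genotypes(cfg0)
  mm0 <- simulate_methylation(g0$geno, plant_effects(g0$geno, cp, cfg0),
                              g0$pedigree, cfg0, cp)
  ped <- g0$pedigree
  mm <- mm0
  expect_lt(abs(twin_cor("MZ") - 0.3), 0.04)
  expect_lt(abs(twin_cor("DZ") - 0.3), 0.04)
})

test_that("summary-statistic generator obeys its scenario contracts", {
  # pleiotropy without noise: one shared ratio at every SNP with signal
  ss <- simulate_summary_stats("pleiotropy", noise = FALSE, b_ratio = 0.4)
  nz <- ss$exposure$b != 0
  expect_equal(ss$outcome$b[nz] / ss$exposure$b[nz],
               rep(0.4, sum(nz)), tolerance = 1e-12)

  # linkage: ratio at the exposure-causal SNP differs from the ratio at the
  # outcome-causal SNP by the factor implied by the marginal-beta formula
  sl <- simulate_summary_stats("linkage", noise = FALSE, ld_rho = 0.9,
                               causal_index = 15, causal2_index = 17,
                               b_exposure = 0.3, b_outcome = 0.15)
  r <- 0.9^2
  ratio_c1 <- sl$outcome$b[15] / sl$exposure$b[15]  # r * b2 / b1
  ratio_c2 <- sl$outcome$b[17] / sl$exposure$b[17]  # b2 / (r * b1)
  expect_equal(ratio_c1 / ratio_c2, r^2, tolerance = 1e-12)

  expect_error(simulate_summary_stats("both"), "arg")
  expect_error(simulate_summary_stats("pleiotropy", n_snps = 10), "25")

  s1 <- simulate_summary_stats("pleiotropy", seed = 42)
  s2 <- simulate_summary_stats("pleiotropy", seed = 42)
  expect_identical(s1, s2)
})
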