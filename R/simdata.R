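#' Simulation configuration for the multi-cohort meQTL study design
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' five-cohort whole-blood study design: cohort sample sizes 394/348/197/83/236,
#' with 88 MZ and 70 DZ twin pairs inside the first (twin) cohort, LD blocks
#' of correlated SNPs, and planted cis/trans meQTL effects of known size.
#'
#' @param n_cohorts Number of cohorts.
#' @param samples_per_cohort Integer vector of per-cohort sample sizes
#'   (recycled to `n_cohorts`).
#' @param n_snps,n_cpgs Number of SNPs / CpG sites (split over two
#'   chromosomes).
#' @param ld_block_size SNPs per LD block; the latent AR(1) correlation
#'   resets at block and chromosome boundaries.
#' @param ld_rho AR(1) parameter of the latent-Gaussian haplotype model,
#'   in \[0, 1).
#' @param maf_range Minor allele frequencies are drawn uniformly from this
#'   interval, within (0, 0.5].
#' @param n_cis_effects,n_trans_effects Number of planted SNP-CpG effects
#'   within / beyond the 1 Mbp cis window.
#' @param effect_size_sd Standard deviation of planted latent-scale betas
#'   (used when `effect_r2` is `NULL`).
#' @param effect_r2 Optional target latent variance explained per planted
#'   effect; when set, |beta| is chosen so that
#'   `beta^2 * 2 * maf * (1 - maf) = effect_r2 / (1 - effect_r2)` relative to
#'   the unit-variance non-genetic latent component (signs random).
#' @param ace_params Named or unnamed numeric triple (A, C, E): shares of
#'   additive-genetic, shared-environment and unique-environment variance in
#'   the latent methylation signal; must sum to 1.
#' @param n_mz_pairs,n_dz_pairs Numbers of monozygotic / dizygotic twin
#'   pairs placed in cohort 1 (the remainder are singletons).
#' @param max_effects_per_cpg Cap on planted effects per CpG.
#' @param cov_effect_sd Standard deviation of per-CpG coefficients on the
#'   (standardised) cell-proportion and smoking confounders.
#' @param batch_sd Standard deviation of per-CpG plate-batch offsets.
#' @param dosage_noise If `TRUE`, add small Gaussian noise to dosages
#'   (imputed-dosage style fractional values), clipped to \[0, 2\].
#' @param snp_spacing,cpg_spacing Base-pair spacing of the synthetic maps.
#' @param seed Single integer; fans out deterministically to per-stage
#'   child seeds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 5,
                       samples_per_cohort = c(394, 348, 197, 83, 236),
                       n_snps = 300,
                       n_cpgs = 400,
                       ld_block_size = 10,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_cis_effects = 60,
                       n_trans_effects = 10,
                       effect_size_sd = 0.5,
                       effect_r2 = NULL,
                       ace_params = c(A = 0.3, C = 0.2, E = 0.5),
                       n_mz_pairs = 88,
                       n_dz_pairs = 70,
                       max_effects_per_cpg = 3,
                       cov_effect_sd = 0.3,
                       batch_sd = 0.2,
                       dosage_noise = FALSE,
                       snp_spacing = 20000,
                       cpg_spacing = 15000,
                       seed = 1) {
  samples_per_cohort <- rep_len(as.integer(samples_per_cohort), n_cohorts)
  counts <- c(n_cohorts = n_cohorts, n_snps = n_snps, n_cpgs = n_cpgs,
              ld_block_size = ld_block_size, samples_per_cohort)
  if (any(counts <= 0)) abort("all counts must be > 0")
  if (ld_block_size > n_snps) abort("ld_block_size cannot exceed n_snps")
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must be in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("maf_range must be (low, high) within (0, 0.5] with low <= high")
  }
  ace_params <- unname(as.numeric(ace_params))
  if (length(ace_params) != 3 || any(ace_params < 0) || any(ace_params > 1) ||
      abs(sum(ace_params) - 1) > 1e-8) {
    abort("ace_params must be three shares in [0, 1] summing to 1")
  }
  if (2L * (n_mz_pairs + n_dz_pairs) > samples_per_cohort[1]) {
    abort("cohort 1 is too small for the requested twin pairs")
  }
  structure(list(n_cohorts = n_cohorts,
                 samples_per_cohort = samples_per_cohort,
                 n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 maf_range = maf_range,
                 n_cis_effects = as.integer(n_cis_effects),
                 n_trans_effects = as.integer(n_trans_effects),
                 effect_size_sd = effect_size_sd, effect_r2 = effect_r2,
                 ace_params = ace_params,
                 n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 max_effects_per_cpg = as.integer(max_effects_per_cpg),
                 cov_effect_sd = cov_effect_sd, batch_sd = batch_sd,
                 dosage_noise = dosage_noise,
                 snp_spacing = snp_spacing, cpg_spacing = cpg_spacing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# latent-Gaussian AR(1) haplotypes: one row per haplotype, one col per SNP;
# allele j carried iff z_j < qnorm(maf_j), z AR(1) within blocks
draw_haplotypes <- function(n_hap, maf, block_id, rho) {
  p <- length(maf)
  z <- matrix(0, n_hap, p)
  z[, 1] <- rnorm(n_hap)
  if (p > 1) {
    for (j in 2:p) {
      if (block_id[j] == block_id[j - 1]) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(n_hap)
      } else {
        z[, j] <- rnorm(n_hap)
      }
    }
  }
  thr <- qnorm(maf)
  z < matrix(thr, n_hap, p, byrow = TRUE)
}

#' Simulate multi-cohort genotypes with LD blocks and twin structure
#'
#' Haplotypes follow a latent-Gaussian AR(1) threshold scheme: within an LD
#' block, consecutive latent values have correlation `ld_rho`, and the allele
#' is carried when the latent value falls below the MAF quantile. MZ twins
#' share both haplotypes exactly; DZ twins share each parental transmission
#' with probability 1/2. Dosages are {0, 1, 2} unless `dosage_noise` is set.
#'
#' @param config A [sim_config()].
#' @return A list with `geno` (a [geno_matrix()] whose `snps$maf` holds the
#'   realised folded MAF) and `pedigree` (tibble: `sample_id`, `cohort`,
#'   `family_id`, `zygosity` in MZ/DZ/singleton).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, "genotypes"), {
    p <- config$n_snps
    chrom <- rep(c("1", "2"), c(ceiling(p / 2), floor(p / 2)))
    pos <- unlist(lapply(split(seq_len(p), chrom), function(i) {
      seq_along(i) * config$snp_spacing
    }), use.names = FALSE)
    ord <- order(as.integer(chrom), pos)
    maf_target <- runif(p, config$maf_range[1], config$maf_range[2])
    # blocks nested within chromosome
    block_id <- paste0(chrom, "_", ceiling(stats::ave(
      seq_len(p), chrom, FUN = seq_along) / config$ld_block_size))

    ped_list <- list()
    dos_list <- list()
    for (co in seq_len(config$n_cohorts)) {
      n <- config$samples_per_cohort[co]
      n_mz <- if (co == 1L) config$n_mz_pairs else 0L
      n_dz <- if (co == 1L) config$n_dz_pairs else 0L
      n_single <- n - 2L * (n_mz + n_dz)
      n_hap <- 2L * n_mz + 4L * n_dz + 2L * n_single
      hap <- draw_haplotypes(n_hap, maf_target, block_id, config$ld_rho)
      dos <- matrix(0L, n, p)
      fam <- character(n)
      zyg <- character(n)
      hi <- 0L; si <- 0L; fi <- 0L
      for (k in seq_len(n_mz)) {
        g <- hap[hi + 1L, ] + hap[hi + 2L, ]; hi <- hi + 2L
        fi <- fi + 1L
        dos[si + 1L, ] <- g; dos[si + 2L, ] <- g
        fam[si + 1:2] <- sprintf("c%d_fam%04d", co, fi)
        zyg[si + 1:2] <- "MZ"
        si <- si + 2L
      }
      for (k in seq_len(n_dz)) {
        fa <- hap[hi + 1:2, , drop = FALSE]
        mo <- hap[hi + 3:4, , drop = FALSE]
        hi <- hi + 4L
        fi <- fi + 1L
        for (tw in 1:2) {
          dos[si + tw, ] <- fa[sample.int(2L, 1L), ] + mo[sample.int(2L, 1L), ]
        }
        fam[si + 1:2] <- sprintf("c%d_fam%04d", co, fi)
        zyg[si + 1:2] <- "DZ"
        si <- si + 2L
      }
      for (k in seq_len(n_single)) {
        dos[si + 1L, ] <- hap[hi + 1L, ] + hap[hi + 2L, ]
        hi <- hi + 2L
        fi <- fi + 1L
        fam[si + 1L] <- sprintf("c%d_fam%04d", co, fi)
        zyg[si + 1L] <- "singleton"
        si <- si + 1L
      }
      ids <- sprintf("c%d_s%04d", co, seq_len(n))
      ped_list[[co]] <- tibble(sample_id = ids,
                               cohort = sprintf("cohort%d", co),
                               family_id = fam, zygosity = zyg)
      dos_list[[co]] <- dos
    }
    dosages <- do.call(rbind, dos_list)
    dosages <- dosages * 1.0
    if (isTRUE(config$dosage_noise)) {
      dosages <- pmin(pmax(dosages + rnorm(length(dosages), sd = 0.05), 0), 2)
    }
    pedigree <- dplyr::bind_rows(ped_list)
    af <- colMeans(dosages) / 2
    maf_real <- pmin(af, 1 - af)
    snps <- tibble(snp_id = sprintf("snp%04d", seq_len(p)),
                   chrom = chrom, pos = pos, ref = "A", alt = "G",
                   maf = maf_real)
    geno <- geno_matrix(dosages, snps,
                        pedigree[, c("sample_id", "cohort")])
    list(geno = geno, pedigree = pedigree)
  })
}

#' Synthetic CpG position map matching the simulated genotype layout
#'
#' @param config A [sim_config()].
#' @return Tibble with `cpg_id`, `chrom`, `pos`, `strand`.
#' @export
simulate_cpg_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_cpgs
  chrom <- rep(c("1", "2"), c(ceiling(p / 2), floor(p / 2)))
  pos <- unlist(lapply(split(seq_len(p), chrom), function(i) {
    seq_along(i) * config$cpg_spacing + 7
  }), use.names = FALSE)
  tibble(cpg_id = sprintf("cg%05d", seq_len(p)),
         chrom = chrom, pos = pos, strand = "+")
}

#' Plant cis and trans meQTL effects with known betas
#'
#' Selects `n_cis_effects` SNP-CpG pairs within 1 Mbp on the same chromosome
#' and `n_trans_effects` pairs violating that rule, drawing latent-scale
#' betas from `N(0, effect_size_sd^2)` (or sizing them to `effect_r2`), with
#' at most `max_effects_per_cpg` planted effects per CpG.
#'
#' @param geno A [geno_matrix()].
#' @param cpg_positions Tibble `cpg_id`, `chrom`, `pos`.
#' @param config A [sim_config()].
#' @return Truth table tibble: `snp_id`, `cpg_id`, `true_beta`, `type`.
#' @export
plant_effects <- function(geno, cpg_positions, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, "effects"), {
    snps <- geno$snps
    pairs <- tidyr::crossing(snp_id = snps$snp_id,
                             cpg_id = cpg_positions$cpg_id) |>
      left_join(snps[, c("snp_id", "chrom", "pos", "maf")], by = "snp_id") |>
      rename(snp_chrom = "chrom", snp_pos = "pos") |>
      left_join(cpg_positions[, c("cpg_id", "chrom", "pos")], by = "cpg_id") |>
      rename(cpg_chrom = "chrom", cpg_pos = "pos")
    pairs$type <- classify_cis_trans(pairs$snp_chrom, pairs$snp_pos,
                                     pairs$cpg_chrom, pairs$cpg_pos)
    pick <- function(cand, n_want, label) {
      if (n_want == 0L) return(cand[0, ])
      cand <- cand[sample.int(nrow(cand)), ]
      counts <- new.env()
      sel <- logical(nrow(cand))
      got <- 0L
      for (i in seq_len(nrow(cand))) {
        cg <- cand$cpg_id[i]
        k <- counts[[cg]] %||% 0L
        if (k < config$max_effects_per_cpg) {
          sel[i] <- TRUE
          counts[[cg]] <- k + 1L
          got <- got + 1L
          if (got == n_want) break
        }
      }
      if (got < n_want) {
        abort(sprintf(
          "insufficient candidate %s pairs: requested %d, placeable %d",
          label, n_want, got))
      }
      cand[sel, ]
    }
    cis <- pick(filter(pairs, .data$type == "cis"),
                config$n_cis_effects, "cis")
    trans <- pick(filter(pairs, .data$type == "trans"),
                  config$n_trans_effects, "trans")
    truth <- bind_rows(cis, trans)
    if (nrow(truth) == 0) {
      return(tibble(snp_id = character(), cpg_id = character(),
                    true_beta = numeric(), type = character()))
    }
    if (!is.null(config$effect_r2)) {
      v <- config$effect_r2 / (1 - config$effect_r2)
      var_g <- 2 * truth$maf * (1 - truth$maf)
      truth$true_beta <- sample(c(-1, 1), nrow(truth), replace = TRUE) *
        sqrt(v / var_g)
    } else {
      truth$true_beta <- rnorm(nrow(truth), sd = config$effect_size_sd)
    }
    truth[, c("snp_id", "cpg_id", "true_beta", "type")]
  })
}

#' Simulate methylation beta-values with ACE structure and confounders
#'
#' Builds, per CpG, a latent value = planted genetic effects + a polygenic
#' additive component (cross-twin correlation 1 for MZ, 0.5 for DZ) scaled to
#' share A + a family-shared component scaled to C + independent noise scaled
#' to E + covariate effects (cell proportions, smoking, plate batch), then
#' maps it through a logistic link with a per-CpG offset so beta-values stay
#' in (0, 1).
#'
#' @param geno A [geno_matrix()].
#' @param truth Truth table from [plant_effects()].
#' @param pedigree Pedigree tibble from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param cpg_positions Optional CpG map; defaults to
#'   [simulate_cpg_positions()].
#' @return List: `meth` (raw-stage [meth_matrix()]), `covars` (covariate
#'   tibble), `latent` (latent-scale matrix, for calibration checks).
#' @export
simulate_methylation <- function(geno, truth, pedigree, config,
                                 cpg_positions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cpg_positions)) cpg_positions <- simulate_cpg_positions(config)
  missing_snp <- setdiff(truth$snp_id, geno$snps$snp_id)
  missing_cpg <- setdiff(truth$cpg_id, cpg_positions$cpg_id)
  if (length(missing_snp) || length(missing_cpg)) {
    abort("truth table references unknown SNPs or CpGs")
  }
  withr::with_seed(child_seed(config$seed, "methylation"), {
    n <- nrow(geno$dosages)
    m <- nrow(cpg_positions)
    A <- config$ace_params[1]; C <- config$ace_params[2]
    E <- config$ace_params[3]

    fam <- factor(pedigree$family_id, levels = unique(pedigree$family_id))
    fam_idx <- as.integer(fam)
    n_fam <- nlevels(fam)
    is_dz <- pedigree$zygosity == "DZ"
    is_mz <- pedigree$zygosity == "MZ"

    # polygenic component: shared draw per family, combined per zygosity
    g_fam <- matrix(rnorm(n_fam * m), n_fam, m)
    g_ind <- matrix(rnorm(n * m), n, m)
    g <- g_ind
    g[is_mz, ] <- g_fam[fam_idx[is_mz], ]
    g[is_dz, ] <- sqrt(0.5) * g_fam[fam_idx[is_dz], ] +
      sqrt(0.5) * g_ind[is_dz, ]

    c_fam <- matrix(rnorm(n_fam * m), n_fam, m)[fam_idx, , drop = FALSE]
    e_ind <- matrix(rnorm(n * m), n, m)
    latent <- sqrt(A) * g + sqrt(C) * c_fam + sqrt(E) * e_ind

    # planted genetic effects on top of the unit-variance ACE component
    if (nrow(truth) > 0) {
      si <- match(truth$snp_id, geno$snps$snp_id)
      ci <- match(truth$cpg_id, cpg_positions$cpg_id)
      for (k in seq_len(nrow(truth))) {
        latent[, ci[k]] <- latent[, ci[k]] +
          truth$true_beta[k] * geno$dosages[, si[k]]
      }
    }

    # covariates: blood cell proportions, smoking, age, sex, plate/chip
    covars <- pedigree |>
      mutate(
        sex = ifelse(runif(n) < 0.6, "F", "M"),
        age = ifelse(.data$cohort == "cohort1", runif(n, 42, 87),
                     runif(n, 44, 65)),
        smoking = rbinom(n, 1, 0.215),
        cd4t = pmin(0.6, pmax(0.01, rnorm(n, 0.199, 0.073))),
        mono = pmin(0.25, pmax(0.005, rnorm(n, 0.05, 0.026))),
        chip_pos = sprintf("R%02d", sample.int(8L, n, replace = TRUE))
      )
    # per-cohort plate index (48 samples per plate)
    covars <- covars |>
      group_by(.data$cohort) |>
      mutate(plate = paste0(.data$cohort, "_p",
                            ceiling(row_number() / 48))) |>
      ungroup()

    cov_design <- cbind(scale(covars$cd4t)[, 1], scale(covars$mono)[, 1],
                        covars$smoking - mean(covars$smoking))
    cov_beta <- matrix(rnorm(3 * m, sd = config$cov_effect_sd), 3, m)
    latent <- latent + cov_design %*% cov_beta
    plate_f <- factor(covars$plate)
    plate_off <- matrix(rnorm(nlevels(plate_f) * m, sd = config$batch_sd),
                        nlevels(plate_f), m)
    latent <- latent + plate_off[as.integer(plate_f), , drop = FALSE]

    offset <- rnorm(m, 0, 1.5)
    beta_vals <- stats::plogis(latent +
                                 matrix(offset, n, m, byrow = TRUE))
    meth <- meth_matrix(beta_vals, cpg_positions[, c("cpg_id", "chrom", "pos")],
                        pedigree[, c("sample_id", "cohort")], stage = "raw")
    list(meth = meth, covars = covars, latent = latent)
  })
}

#' Draw twin-pair values directly from the ACE covariance model
#'
#' Bivariate-normal pairs with unit variance, cross-twin covariance
#' `A + C` (MZ) and `A/2 + C` (DZ). Used for calibration and recovery checks
#' of [fit_ace()].
#'
#' @param A,C,E Variance shares summing to 1.
#' @param n_mz,n_dz Numbers of pairs.
#' @param seed Integer seed.
#' @return List with `mz` (`n_mz` x 2) and `dz` (`n_dz` x 2) matrices.
#' @export
simulate_twin_pairs <- function(A, C, E = 1 - A - C, n_mz, n_dz, seed = 1) {
  stopifnot(abs(A + C + E - 1) < 1e-8, A >= 0, C >= 0, E >= 0)
  withr::with_seed(as.integer(seed), {
    draw <- function(n, r) {
      z1 <- rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
      cbind(z1, z2)
    }
    list(mz = draw(n_mz, min(1, A + C)), dz = draw(n_dz, A / 2 + C))
  })
}
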