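test_that("Hardy-Weinberg exact test matches enumeration", {
  # two samples, two alt alleles: P(het = 0) = 1/3, P(het = 2) = 2/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # monomorphic: single attainable configuration
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # balanced table vs the enumeration oracle
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  for (cfg in list(c(3, 5, 2), c(40, 2, 8), c(0, 10, 0), c(12, 1, 30))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 oracle_hwe(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("genotype QC applies the MAF boundary strictly and reports reasons", {
  # 500 samples; SNP A: 9 het carriers -> MAF 0.009 (excluded);
  # SNP B: 10 -> MAF 0.010 (retained, strict <)
  n <- 500
  mk <- function(k) c(rep(1, k), rep(0, n - k))
  # SNP C violates HWE: all-het at 50/50 alleles
  hwe_bad <- rep(1, n)
  d <- cbind(a = mk(9), b = mk(10), c = hwe_bad,
             ok = rep(c(0, 1, 2, 1, 0), n / 5))
  g <- geno_matrix(d,
                   tibble::tibble(snp_id = colnames(d), chrom = "1",
                                  pos = 1:4 * 1000, ref = "A", alt = "G",
                                  maf = NA),
                   tibble::tibble(sample_id = paste0("s", 1:n),
                                  cohort = "c1"))
  fg <- filter_genotypes(g)
  expect_identical(fg$geno$snps$snp_id, c("b", "ok"))
  rep <- setNames(fg$report$n, fg$report$reason)
  expect_equal(unname(rep["snp_maf"]), 1)
  expect_equal(unname(rep["snp_hwe"]), 1)
  expect_equal(unname(rep["sample_missingness"]), 0)

  # clean matrix passes unchanged, and filtering is idempotent
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 300, n_snps = 30,
                    ld_block_size = 5, n_mz_pairs = 0, n_dz_pairs = 0,
                    maf_range = c(0.2, 0.4), seed = 2)
  gg <- simulate_genotypes(cfg)$geno
  f1 <- filter_genotypes(gg)
  f2 <- filter_genotypes(f1$geno)
  expect_identical(f1$geno$dosages, f2$geno$dosages)
  expect_equal(sum(f2$report$n), 0)

  # sample missingness handled before SNP statistics
  d2 <- gg$dosages
  d2[1, ] <- NA  # sample fully missing
  d2[2:4, 1] <- NA  # SNP 1 10% missing among remaining? (3/299 ~ 1%)
  g2 <- geno_matrix(d2, gg$snps, gg$samples)
  f3 <- filter_genotypes(g2, snp_miss_max = 0.005)
  rep3 <- setNames(f3$report$n, f3$report$reason)
  expect_equal(unname(rep3["sample_missingness"]), 1)
  expect_equal(unname(rep3["snp_missingness"]), 1)
})

test_that("probe QC respects thresholds, masks and idempotence", {
  n <- 100; m <- 100
  v <- matrix(runif(n * m), n, m)
  # probes 1..3 over-missing (6%), probes 4..10 masked (one overlaps: 3)
  v[1:6, 1:3] <- NA
  meth <- meth_matrix(v, tibble::tibble(cpg_id = paste0("cg", 1:m),
                                        chrom = "1", pos = 1:m * 100),
                      tibble::tibble(sample_id = paste0("s", 1:n),
                                     cohort = "c1"))
  fp <- filter_probes(meth, mask_list = paste0("cg", 3:9))
  expect_equal(ncol(fp$meth$values), 100 - 3 - 7 + 1)
  rep <- setNames(fp$report$n, fp$report$reason)
  expect_equal(unname(rep["probe_missingness"]), 3)
  expect_equal(unname(rep["probe_masked"]), 7)
  # exactly 5% missing is retained (strict >)
  v2 <- matrix(runif(n * m), n, m)
  v2[1:5, 1] <- NA
  meth2 <- meth_matrix(v2, meth$cpgs, meth$samples)
  expect_equal(ncol(filter_probes(meth2)$meth$values), m)
  # identity on clean input
  f1 <- filter_probes(meth2, probe_miss_max = 0.10)
  f2 <- filter_probes(f1$meth, probe_miss_max = 0.10)
  expect_identical(f1$meth$values, f2$meth$values)
})

test_that("inverse normal transform follows the Blom formula with ties", {
  expect_equal(inverse_normal_transform(c(1, 2, 3))[2], 0)
  # ties at average rank, direct formula plug-in
  x <- c(5, 1, 1, 9)
  got <- inverse_normal_transform(x)
  want <- qnorm((c(3, 1.5, 1.5, 4) - 0.375) / 4.25)
  expect_equal(got, want, tolerance = 1e-12)
  # symmetry of rank scores: mean 0, negligible skew for tie-free input
  set.seed(1)
  y <- rexp(101)
  ty <- inverse_normal_transform(y)
  expect_equal(mean(ty), 0, tolerance = 1e-10)
  expect_lt(abs(mean((ty - mean(ty))^3)), 1e-8)
  # monotone in ranks
  expect_equal(cor(ty, y, method = "spearman"), 1)
  # missing preserved
  z <- c(1, NA, 3, 2)
  expect_true(is.na(inverse_normal_transform(z)[2]))
  expect_error(inverse_normal_transform(c(1, 1, 1)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "3 non-missing")
})

test_that("covariate residualisation projects exactly and matches the one-way oracle", {
  set.seed(4)
  n <- 80
  covars <- tibble::tibble(sample_id = paste0("s", 1:n),
                           age = rnorm(n, 50, 5),
                           cd4t = runif(n, 0.1, 0.3),
                           plate = rep(c("p1", "p2"), each = n / 2),
                           const = 1)
  mkmeth <- function(v, stage = "INT") {
    structure(list(values = v,
                   cpgs = tibble::tibble(cpg_id = paste0("cg", seq_len(ncol(v))),
                                         chrom = "1",
                                         pos = seq_len(ncol(v)) * 100),
                   samples = tibble::tibble(sample_id = paste0("s", 1:n),
                                            cohort = "c1"),
                   stage = stage), class = "meth_matrix")
  }
  # constant covariates: residuals are the centred input
  v <- matrix(rnorm(n * 3), n, 3)
  adj <- adjust_methylation(mkmeth(v), covars, fixed = "const")
  expect_equal(adj$values, scale(v, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(adj$stage, "residual")

  # planted noiseless covariate effect removed exactly
  v2 <- matrix(0.7 * covars$age + 2 * covars$cd4t, n, 2)
  adj2 <- adjust_methylation(mkmeth(v2 + 0), covars,
                             fixed = c("age", "cd4t"))
  expect_lt(max(abs(adj2$values)), 1e-8)
  # with noise, residual correlation with the planted covariate vanishes
  v2n <- v2 + matrix(rnorm(n * 2), n, 2)
  adj2n <- adjust_methylation(mkmeth(v2n), covars,
                              fixed = c("age", "cd4t"))
  expect_lt(abs(cor(adj2n$values[, 1], covars$age)), 1e-10)

  # residuals orthogonal to every design column
  v3 <- matrix(rnorm(n * 5), n, 5)
  adj3 <- adjust_methylation(mkmeth(v3), covars,
                             fixed = c("age", "cd4t"), grouping = "plate")
  X <- stats::model.matrix(~ age + cd4t + plate, data = covars)
  expect_lt(max(abs(crossprod(X, adj3$values))), 1e-8 * n)

  # balanced 2-plate design: random-intercept mode equals the fixed mode up
  # to the closed-form one-way shrinkage factor
  delta <- 1.3
  y <- rnorm(n) + delta * (covars$plate == "p2")
  vy <- matrix(y, n, 1)
  fixed_res <- adjust_methylation(mkmeth(vy), covars, grouping = "plate",
                                  grouping_mode = "fixed")$values[, 1]
  rand_res <- adjust_methylation(mkmeth(vy), covars, grouping = "plate",
                                 grouping_mode = "random")$values[, 1]
  # oracle: one-way ANOVA method-of-moments variance components
  yc <- y - mean(y)
  gm <- tapply(yc, covars$plate, mean)
  ng <- n / 2
  sigma2 <- sum((yc - gm[covars$plate])^2) / (n - 2)
  msb <- ng * sum(gm^2) / 1
  tau2 <- max(0, (msb - sigma2) / ng)
  shrink <- tau2 / (tau2 + sigma2 / ng)
  oracle_res <- yc - shrink * gm[covars$plate]
  expect_equal(unname(rand_res), as.numeric(oracle_res), tolerance = 1e-10)
  expect_equal(unname(fixed_res), as.numeric(yc - gm[covars$plate]),
               tolerance = 1e-10)

  # rank-deficient design warns and drops aliased columns
  covars$dup <- covars$age
  expect_warning(adjust_methylation(mkmeth(v), covars,
                                    fixed = c("age", "dup")),
                 "rank-deficient")
})
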