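test_that("DerSimonian-Laird pooling matches the hand-derived cases", {
  # identical studies: Q = 0, fixed-effect pooling
  m1 <- dl_meta(c(1, 1), c(0.5, 0.5))
  expect_equal(m1$tau2, 0)
  expect_equal(m1$beta, 1)
  expect_equal(m1$se, 0.5 / sqrt(2), tolerance = 1e-12)
  expect_equal(m1$directions, "++")

  # single study passes through
  m2 <- dl_meta(0.7, 0.2)
  expect_equal(m2$beta, 0.7)
  expect_equal(m2$se, 0.2)
  expect_equal(m2$k, 1)

  # b = (0, 2), se = (1, 1): Q = 2, tau2 = 1, pooled b = 1, pooled se = 1
  m3 <- dl_meta(c(0, 2), c(1, 1))
  expect_equal(m3$tau2, 1, tolerance = 1e-12)
  expect_equal(m3$beta, 1, tolerance = 1e-12)
  expect_equal(m3$se, 1, tolerance = 1e-12)
  expect_equal(m3$directions, "++")

  expect_error(dl_meta(numeric(0), numeric(0)), "no studies")
  expect_error(dl_meta(c(1, 1), c(0.5, 0)), "> 0")
})

test_that("dl_meta equals the brute-force oracle and metafor on random configurations", {
  set.seed(20)
  for (i in 1:300) {
    k <- sample(1:5, 1)
    b <- rnorm(k)
    s <- runif(k, 0.1, 2)
    got <- dl_meta(b, s)
    want <- oracle_dl(b, s)
    expect_equal(got$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-10)
  }
  skip_if_not_installed("metafor")
  for (i in 1:20) {
    k <- sample(2:5, 1)
    b <- rnorm(k)
    s <- runif(k, 0.1, 2)
    got <- dl_meta(b, s)
    rma <- metafor::rma(yi = b, sei = s, method = "DL")
    expect_equal(got$beta, as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(got$se, rma$se, tolerance = 1e-8)
    expect_equal(got$tau2, rma$tau2, tolerance = 1e-8)
  }
})

test_that("vectorised meta_analyse agrees with per-pair dl_meta", {
  set.seed(21)
  recs <- tidyr::crossing(snp_id = paste0("snp", 1:6),
                          cpg_id = paste0("cg", 1:4),
                          cohort = paste0("c", 1:3)) |>
    dplyr::mutate(type = "cis", beta = rnorm(dplyr::n()),
                  se = runif(dplyr::n(), 0.1, 1), p = runif(dplyr::n()),
                  n = 100) |>
    dplyr::slice_sample(prop = 0.7)
  mt <- meta_analyse(recs)
  for (i in sample(nrow(mt), 8)) {
    sub <- recs[recs$snp_id == mt$snp_id[i] & recs$cpg_id == mt$cpg_id[i], ]
    sub <- sub[order(sub$cohort), ]
    ref <- dl_meta(sub$beta, sub$se)
    expect_equal(mt$beta[i], ref$beta, tolerance = 1e-10)
    expect_equal(mt$se[i], ref$se, tolerance = 1e-10)
    expect_equal(mt$tau2[i], ref$tau2, tolerance = 1e-10)
    expect_equal(mt$k[i], ref$k)
    expect_identical(mt$directions[i], ref$directions)
  }
})

test_that("consistency filter keeps >= 2 cohorts with one direction only", {
  mk <- function(k, dirs) tibble::tibble(
    snp_id = "s", cpg_id = "c", type = "cis", beta = 1, se = 1, p = 0.5,
    tau2 = 0, k = k, directions = dirs)
  expect_equal(nrow(consistency_filter(mk(1, "+"))), 0)
  expect_equal(nrow(consistency_filter(mk(3, "++-"))), 0)
  expect_equal(nrow(consistency_filter(mk(2, "--"))), 1)
  expect_equal(nrow(consistency_filter(mk(2, "++"))), 1)
  # never grows, idempotent
  mixed <- dplyr::bind_rows(mk(1, "+"), mk(2, "+-"), mk(4, "++++"))
  f1 <- consistency_filter(mixed)
  expect_lte(nrow(f1), nrow(mixed))
  expect_identical(consistency_filter(f1), f1)
})

test_that("family-preserving permutation keeps blocks and multisets intact", {
  v <- matrix(seq_len(10 * 3), 10, 3)
  samples <- tibble::tibble(sample_id = paste0("s", 1:10), cohort = "c1")
  meth <- structure(list(values = v,
                         cpgs = tibble::tibble(cpg_id = paste0("cg", 1:3),
                                               chrom = "1", pos = 1:3),
                         samples = samples, stage = "residual"),
                    class = "meth_matrix")
  # all singletons: any permutation, values conserved per CpG
  ped <- tibble::tibble(sample_id = samples$sample_id,
                        family_id = samples$sample_id,
                        zygosity = "singleton")
  pm <- permute_cohort(meth, ped, seed = 5)
  for (j in 1:3) expect_setequal(pm$values[, j], v[, j])
  expect_identical(permute_cohort(meth, ped, seed = 5)$values, pm$values)

  # two MZ pairs: twins never separated
  ped2 <- tibble::tibble(
    sample_id = samples$sample_id,
    family_id = c("f1", "f1", "f2", "f2", paste0("g", 5:10)),
    zygosity = c(rep("MZ", 4), rep("singleton", 6)))
  for (s in 1:10) {
    p2 <- permute_cohort(meth, ped2, seed = s)
    # rows 1-2 hold some family's two members, in order
    expect_true(all(p2$values[2, ] - p2$values[1, ] == 1))
    expect_true(all(p2$values[4, ] - p2$values[3, ] == 1))
    # family rows land in family slots
    expect_true(all(p2$values[1, 1] %in% c(1, 3)))
  }
})

test_that("permutation FDR reproduces the hand example and its invariances", {
  obs <- c(1e-6, 0.002, 0.004, 0.2)
  nulls <- list(c(0.001, 0.3, 0.6, 0.9), c(0.05, 0.4, 0.7, 0.95))
  fc <- permutation_fdr(obs, nulls, target = 0.05)
  cv <- fc$curve
  expect_equal(cv$fdr[cv$threshold == 1e-6], 0)
  expect_equal(cv$fdr[cv$threshold == 0.002], 0.25)
  expect_equal(fc$selected_threshold, 1e-6)
  expect_equal(glance(fc)$n_significant, 1L)

  # null sets entirely above all observed p: FDR identically 0
  fc0 <- permutation_fdr(obs, list(c(0.5, 0.9)), target = 0.05)
  expect_true(all(fc0$curve$fdr == 0))
  expect_equal(fc0$selected_threshold, 0.2)

  # duplicating the null sets leaves the curve unchanged
  fc2 <- permutation_fdr(obs, c(nulls, nulls), target = 0.05)
  expect_equal(fc$curve$fdr, fc2$curve$fdr)

  # no observed p: threshold undefined
  fce <- permutation_fdr(numeric(0), nulls)
  expect_true(is.na(fce$selected_threshold))
})

test_that("null p-values from permuted cohorts are uniform", {
  tiny <- make_tiny_cohorts(seed = 8, n_cohorts = 1, n = 100, n_cis = 0,
                            n_mz = 0, n_dz = 0)
  ps <- c()
  for (b in 1:20) {
    pm <- permute_cohort(tiny$cohorts[[1]]$meth, tiny$pedigrees[[1]],
                         seed = b * 31)
    recs <- scan_cohort(tiny$cohorts[[1]]$geno, pm, p_cis = 1, p_trans = 1)
    ps <- c(ps, recs$p)
  }
  # marginal uniformity of the permutation null (subsample to soften the
  # dependence between pairs sharing a SNP or CpG)
  set.seed(99)
  expect_gt(ks.test(sample(ps, 5000), "punif")$p.value, 0.01)
})

test_that("Bonferroni, variance explained and the heritability regression behave", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")

  expect_equal(variance_explained(0.4, 0.5), 0.08, tolerance = 1e-12)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_error(variance_explained(0.5, 0.6), "maf")
  # empirical oracle: noiseless y = beta * g
  set.seed(30)
  n <- 5000
  g <- rbinom(n, 2, 0.25)
  beta <- 0.3
  y <- beta * g + rnorm(n, sd = sqrt(1 - variance_explained(beta, 0.25)))
  y <- y / sd(y)
  emp <- cor(y, g)^2
  expect_lt(abs(variance_explained(beta, 0.25) - emp), 2 / sqrt(n))

  # regression: R^2 = 0 when A identical across groups, 1 when exact
  status <- tibble::tibble(cpg_id = paste0("cg", 1:40),
                           has_cis = rep(c(TRUE, FALSE), 20),
                           has_trans = rep(c(TRUE, TRUE, FALSE, FALSE), 10))
  ace_flat <- tibble::tibble(cpg_id = status$cpg_id, A = 0.3,
                             converged = TRUE)
  expect_equal(heritability_meqtl_regression(ace_flat, status)$r_squared, 0)
  ace_exact <- tibble::tibble(cpg_id = status$cpg_id,
                              A = 0.1 + 0.2 * status$has_cis +
                                0.1 * status$has_trans,
                              converged = TRUE)
  expect_equal(heritability_meqtl_regression(ace_exact, status)$r_squared, 1)

  # planted group means recovered (scaled-down version of the study design)
  set.seed(31)
  n_cpg <- 20000
  has_cis <- runif(n_cpg) < 0.35
  has_trans <- runif(n_cpg) < 0.05
  mu <- ifelse(!has_cis & !has_trans, 0.085,
               ifelse(has_cis & !has_trans, 0.238,
                      ifelse(!has_cis & has_trans, 0.295, 0.435)))
  ace_sim <- tibble::tibble(cpg_id = paste0("cg", seq_len(n_cpg)),
                            A = mu + rnorm(n_cpg, 0, 0.15),
                            converged = TRUE)
  hr <- heritability_meqtl_regression(
    ace_sim, tibble::tibble(cpg_id = ace_sim$cpg_id, has_cis = has_cis,
                            has_trans = has_trans))
  gm <- setNames(hr$group_means$mean_A, hr$group_means$group)
  expect_lt(abs(unname(gm["none"]) - 0.085), 0.02)
  expect_lt(abs(unname(gm["cis_only"]) - 0.238), 0.02)
  expect_lt(abs(unname(gm["trans_only"]) - 0.295), 0.02)
  expect_lt(abs(unname(gm["both"]) - 0.435), 0.02)
  expect_s3_class(tidy(hr), "tbl_df")
  expect_equal(nrow(glance(hr)), 1)
  expect_error(heritability_meqtl_regression(
    ace_flat, dplyr::mutate(status, has_cis = TRUE, has_trans = TRUE)),
    "groups")
})
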