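#' DerSimonian-Laird random-effects meta-analysis for one SNP-CpG pair
#'
#' Inverse-variance weighting with the DerSimonian-Laird moment estimator of
#' the between-cohort variance: fixed weights `w = 1/se^2`,
#' `Q = sum w (b - b_fixed)^2`,
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random weights
#' `w* = 1/(se^2 + tau2)`, pooled `b = sum w* b / sum w*`,
#' `se = (sum w*)^{-1/2}`, two-sided normal p-value. A single study is
#' returned unchanged (`tau2 = 0`).
#'
#' @param beta,se Per-cohort effect estimates and standard errors.
#' @return One-row tibble: `beta`, `se`, `p`, `tau2`, `k`, `directions`
#'   (per-cohort sign string, `+`/`-`).
#' @export
dl_meta <- function(beta, se) {
  k <- length(beta)
  if (k == 0) abort("no studies to meta-analyse")
  if (any(!is.finite(beta)) || any(!is.finite(se))) {
    abort("beta and se must be finite")
  }
  if (any(se <= 0)) abort("all standard errors must be > 0")
  w <- 1 / se^2
  b_fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fixed)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (k > 1 && denom > 0) max(0, (Q - (k - 1)) / denom) else 0
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * beta) / sum(ws)
  s <- sqrt(1 / sum(ws))
  dirs <- paste(ifelse(beta >= 0, "+", "-"), collapse = "")
  tibble(beta = b, se = s, p = 2 * pnorm(-abs(b / s)), tau2 = tau2, k = k,
         directions = dirs)
}

#' Meta-analyse per-cohort association records across all pairs
#'
#' Vectorised DerSimonian-Laird pooling of [scan_cohort()] candidate records
#' grouped by SNP-CpG pair.
#'
#' @param records Tibble of per-cohort records (`snp_id`, `cpg_id`, `type`,
#'   `cohort`, `beta`, `se`, `p`).
#' @return Tibble of meta results: one row per pair with pooled `beta`,
#'   `se`, `p`, `tau2`, `k`, `directions`.
#' @export
meta_analyse <- function(records) {
  if (any(records$se <= 0)) abort("all standard errors must be > 0")
  records |>
    arrange(.data$snp_id, .data$cpg_id, .data$cohort) |>
    group_by(.data$snp_id, .data$cpg_id, .data$type) |>
    summarise(
      k = n(),
      directions = paste(ifelse(.data$beta >= 0, "+", "-"), collapse = ""),
      w_sum = sum(1 / .data$se^2),
      b_fixed = sum(.data$beta / .data$se^2) / w_sum,
      Q = sum((.data$beta - b_fixed)^2 / .data$se^2),
      denom = w_sum - sum(1 / .data$se^4) / w_sum,
      tau2 = ifelse(k > 1 & denom > 0, pmax(0, (Q - (k - 1)) / denom), 0),
      pooled_beta = sum(.data$beta / (.data$se^2 + tau2)) /
        sum(1 / (.data$se^2 + tau2)),
      pooled_se = sqrt(1 / sum(1 / (.data$se^2 + tau2))),
      .groups = "drop") |>
    mutate(beta = .data$pooled_beta, se = .data$pooled_se,
           p = 2 * pnorm(-abs(.data$beta / .data$se))) |>
    select("snp_id", "cpg_id", "type", "beta", "se", "p", "tau2", "k",
           "directions")
}

#' Keep pairs found as candidates in two or more cohorts with one direction
#'
#' @param meta_results Output of [meta_analyse()] (needs `k` and
#'   `directions`).
#' @return Filtered meta results.
#' @export
consistency_filter <- function(meta_results) {
  keep <- meta_results$k >= 2 &
    (meta_results$directions == strrep("+", meta_results$k) |
       meta_results$directions == strrep("-", meta_results$k))
  meta_results[keep, , drop = FALSE]
}

#' Family-preserving permutation of methylation sample labels
#'
#' Shuffles methylation profiles across samples while keeping family blocks
#' intact: within each family-size class, whole families are reassigned to
#' the sample slots of other families of the same size (singleton-only
#' pedigrees reduce to a full sample shuffle). Genotypes are untouched.
#'
#' @param meth A [meth_matrix()].
#' @param pedigree Pedigree tibble with `sample_id`, `family_id` (used for
#'   the methylation samples; samples absent from the pedigree are treated
#'   as singletons).
#' @param seed Integer seed.
#' @return A [meth_matrix()] with permuted rows (sample labels retained).
#' @export
permute_cohort <- function(meth, pedigree = NULL, seed = 1) {
  stopifnot(inherits(meth, "meth_matrix"))
  n <- nrow(meth$values)
  fam <- if (is.null(pedigree)) {
    seq_len(n)
  } else {
    f <- pedigree$family_id[match(meth$samples$sample_id,
                                  pedigree$sample_id)]
    f[is.na(f)] <- paste0(".single", seq_len(sum(is.na(f))))
    f
  }
  withr::with_seed(as.integer(seed), {
    blocks <- split(seq_len(n), fam)
    sizes <- lengths(blocks)
    new_order <- integer(n)
    for (s in unique(sizes)) {
      cls <- which(sizes == s)
      perm <- if (length(cls) > 1) sample(cls) else cls
      # family in slot cls[i] receives the rows of family perm[i]
      from <- unlist(blocks[perm], use.names = FALSE)
      to <- unlist(blocks[cls], use.names = FALSE)
      new_order[to] <- from
    }
  })
  out <- meth
  out$values <- meth$values[new_order, , drop = FALSE]
  rownames(out$values) <- meth$samples$sample_id
  out
}

#' Permutation-based FDR curve and threshold selection
#'
#' Estimates, on the grid of observed p-values,
#' `FDR(t) = [(1/B) * sum_b #{p_null_b <= t}] / #{p_obs <= t}` and selects
#' the largest threshold with estimated FDR at or below `target`. The null
#' sets must come from the identical scan + meta-analysis + filter pipeline
#' run on permuted data.
#'
#' @param observed_p Observed p-values (one association type at a time).
#' @param null_p_sets List of B numeric vectors of null p-values.
#' @param target FDR target.
#' @return Object of class `fdr_curve`: list with `curve` (tibble
#'   `threshold`, `n_obs`, `mean_null`, `fdr`), `selected_threshold`
#'   (NA if no grid point qualifies), `target`, `B`.
#' @export
permutation_fdr <- function(observed_p, null_p_sets, target = 0.05) {
  if (length(null_p_sets) < 1) abort("need at least one null set")
  if (length(observed_p) == 0) {
    out <- list(curve = tibble(threshold = numeric(), n_obs = integer(),
                               mean_null = numeric(), fdr = numeric()),
                selected_threshold = NA_real_, target = target,
                B = length(null_p_sets))
    class(out) <- "fdr_curve"
    return(out)
  }
  grid <- sort(unique(observed_p))
  obs_sorted <- sort(observed_p)
  n_obs <- findInterval(grid, obs_sorted)
  null_counts <- vapply(null_p_sets, function(np) {
    findInterval(grid, sort(np))
  }, numeric(length(grid)))
  mean_null <- if (length(grid) == 1) mean(null_counts) else
    rowMeans(matrix(null_counts, nrow = length(grid)))
  fdr <- mean_null / n_obs
  ok <- fdr <= target
  sel <- if (any(ok)) max(grid[ok]) else NA_real_
  out <- list(curve = tibble(threshold = grid, n_obs = n_obs,
                             mean_null = mean_null, fdr = fdr),
              selected_threshold = sel, target = target,
              B = length(null_p_sets))
  class(out) <- "fdr_curve"
  out
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("<fdr_curve> B = %d permutations, target %.3g\n", x$B,
              x$target))
  if (is.na(x$selected_threshold)) {
    cat("  no threshold attains the target (selection undefined)\n")
  } else {
    n_sig <- x$curve$n_obs[x$curve$threshold == x$selected_threshold]
    cat(sprintf("  selected threshold %.3g (%d observed pairs pass)\n",
                x$selected_threshold, n_sig))
  }
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_tests < 1) abort("n_tests must be >= 1")
  alpha / n_tests
}

#' Methylation variance explained by a meQTL
#'
#' Under Hardy-Weinberg genotype frequencies and a unit-variance
#' (residualised/INT) phenotype, a dosage effect `beta` at minor allele
#' frequency `maf` explains `R^2 = 2 maf (1 - maf) beta^2` of the variance
#' (capped at 1).
#'
#' @param beta Per-allele effect estimate.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Variance explained.
#' @export
variance_explained <- function(beta, maf) {
  if (any(maf <= 0 | maf > 0.5)) abort("maf must be in (0, 0.5]")
  pmin(1, 2 * maf * (1 - maf) * beta^2)
}

#' Regression of CpG heritability on meQTL status
#'
#' OLS of the additive-genetic share `A` on binary indicators for having at
#' least one cis-meQTL and at least one trans-meQTL, summarising how much of
#' the heritability variance the detected meQTLs explain, together with the
#' four group means (none / cis-only / trans-only / both).
#'
#' @param ace ACE estimates tibble (`cpg_id`, `A`, `converged`).
#' @param meqtl_status Tibble `cpg_id`, `has_cis`, `has_trans` (logical).
#' @return Object of class `herit_meqtl_reg`: list with `fit` (the `lm`),
#'   `r_squared`, `f_statistic`, `df`, `p`, `group_means` tibble.
#' @export
heritability_meqtl_regression <- function(ace, meqtl_status) {
  df <- as_tibble(ace) |>
    filter(.data$converged) |>
    inner_join(meqtl_status, by = "cpg_id")
  if (nrow(df) < 3) abort("need at least 3 CpGs with status")
  if (dplyr::n_distinct(paste(df$has_cis, df$has_trans)) < 2) {
    abort("need at least 2 meQTL status groups")
  }
  fit <- lm(A ~ has_cis + has_trans, data = df)
  sm <- summary(fit)
  # constant response: no variance to explain
  if (var(df$A) < 1e-12) {
    sm$r.squared <- 0
    sm$fstatistic <- c(value = 0, numdf = 2,
                       dendf = nrow(df) - 3)
  }
  gm <- df |>
    mutate(group = dplyr::case_when(
      !.data$has_cis & !.data$has_trans ~ "none",
      .data$has_cis & !.data$has_trans ~ "cis_only",
      !.data$has_cis & .data$has_trans ~ "trans_only",
      TRUE ~ "both")) |>
    group_by(.data$group) |>
    summarise(mean_A = mean(.data$A), sd_A = sd(.data$A), n = n(),
              .groups = "drop")
  fstat <- sm$fstatistic
  out <- list(fit = fit, r_squared = sm$r.squared,
              f_statistic = unname(fstat[1]),
              df = unname(fstat[2:3]),
              p = unname(pf(fstat[1], fstat[2], fstat[3],
                            lower.tail = FALSE)),
              group_means = gm)
  class(out) <- "herit_meqtl_reg"
  out
}

#' @export
print.herit_meqtl_reg <- function(x, ...) {
  cat(sprintf(
    "<herit_meqtl_reg> meQTL status explains %.1f%% of heritability variance (F(%d, %d) = %.3g, p = %.3g)\n",
    100 * x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p))
  print(x$group_means)
  invisible(x)
}
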