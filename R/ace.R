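# bivariate-normal log-likelihood for exchangeable twin pairs via
# sufficient statistics; sigma = [[v, c], [c, v]]
pair_suffstats <- function(pairs) {
  list(n = nrow(pairs),
       s1 = sum(pairs), s11 = sum(pairs^2), s12 = sum(pairs[, 1] * pairs[, 2]))
}

pair_loglik <- function(st, mu, v, cv) {
  det <- v^2 - cv^2
  if (det <= 0 || v <= 0) return(-Inf)
  # sum (y - mu)' Sigma^-1 (y - mu) expanded with sufficient stats
  a <- v / det
  b <- -cv / det
  q <- a * (st$s11 - 2 * mu * st$s1 + 2 * st$n * mu^2) +
    2 * b * (st$s12 - mu * st$s1 + st$n * mu^2)
  -st$n * log(2 * pi) - st$n / 2 * log(det) - q / 2
}

ace_negll <- function(par, st_mz, st_dz) {
  mu <- par[1]; a2 <- par[2]; c2 <- par[3]; e2 <- par[4]
  v <- a2 + c2 + e2
  ll <- pair_loglik(st_mz, mu, v, a2 + c2) +
    pair_loglik(st_dz, mu, v, a2 / 2 + c2)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Falconer closed-form ACE point from twin correlations
#'
#' `A = 2 (rMZ - rDZ)`, `C = rMZ - A`, `E = 1 - A - C`, with negative
#' components clipped at zero and the shares renormalised to sum to 1.
#' Serves as an analytic starting point and oracle for [fit_ace()].
#'
#' @param r_mz,r_dz Cross-twin correlations, in \[-1, 1\].
#' @return Named numeric vector `(A, C, E)`.
#' @export
falconer_estimate <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  A <- max(0, 2 * (r_mz - r_dz))
  C <- max(0, r_mz - A)
  E <- max(0, 1 - A - C)
  s <- A + C + E
  if (s == 0) return(c(A = 0, C = 0, E = 1))
  c(A = A / s, C = C / s, E = E / s)
}

#' Maximum-likelihood ACE variance decomposition for one CpG
#'
#' Fits the classical-twin ACE model by maximising the bivariate-normal pair
#' likelihood with common mean, total variance `a2 + c2 + e2`, MZ covariance
#' `a2 + c2` and DZ covariance `a2/2 + c2`, under non-negativity bounds on
#' the variance components. Values are standardised to unit variance before
#' fitting (shares are scale-invariant), and two starts are used: the
#' Falconer plug-in point and equal thirds. Non-finite likelihoods at both
#' starts mark the fit as non-converged with missing shares.
#'
#' @param mz_pairs,dz_pairs Numeric matrices (pairs x 2) of residual-stage
#'   methylation for MZ and DZ twin pairs.
#' @param cpg_id Optional identifier carried into the result.
#' @return One-row tibble: `cpg_id`, `A`, `C`, `E`, `loglik`, `converged`.
#' @export
fit_ace <- function(mz_pairs, dz_pairs, cpg_id = NA_character_) {
  mz_pairs <- as.matrix(mz_pairs); dz_pairs <- as.matrix(dz_pairs)
  stopifnot(ncol(mz_pairs) == 2, ncol(dz_pairs) == 2)
  failed <- tibble(cpg_id = cpg_id, A = NA_real_, C = NA_real_, E = NA_real_,
                   loglik = NA_real_, converged = FALSE)
  all_v <- c(mz_pairs, dz_pairs)
  s <- sd(all_v)
  if (!is.finite(s) || s == 0) return(failed)
  mz <- (mz_pairs - mean(all_v)) / s
  dz <- (dz_pairs - mean(all_v)) / s
  st_mz <- pair_suffstats(mz)
  st_dz <- pair_suffstats(dz)
  r_mz <- suppressWarnings(cor(mz[, 1], mz[, 2]))
  r_dz <- suppressWarnings(cor(dz[, 1], dz[, 2]))
  if (!is.finite(r_mz)) r_mz <- 0
  if (!is.finite(r_dz)) r_dz <- 0
  falc <- falconer_estimate(max(-1, min(1, r_mz)), max(-1, min(1, r_dz)))
  starts <- list(c(0, pmax(falc, 0.01)), c(0, 1 / 3, 1 / 3, 1 / 3))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, ace_negll, st_mz = st_mz, st_dz = st_dz,
            method = "L-BFGS-B",
            lower = c(-Inf, 0, 0, 1e-8), upper = c(Inf, 10, 10, 10)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9 &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) return(failed)
  a2 <- best$par[2]; c2 <- best$par[3]; e2 <- best$par[4]
  tot <- a2 + c2 + e2
  tibble(cpg_id = cpg_id, A = a2 / tot, C = c2 / tot, E = e2 / tot,
         loglik = -best$value, converged = TRUE)
}

# log-likelihood of standardised data at given shares (used in tests)
ace_loglik_at <- function(mz_pairs, dz_pairs, shares) {
  all_v <- c(mz_pairs, dz_pairs)
  mz <- (as.matrix(mz_pairs) - mean(all_v)) / sd(all_v)
  dz <- (as.matrix(dz_pairs) - mean(all_v)) / sd(all_v)
  pair_loglik(pair_suffstats(mz), 0, 1, shares[1] + shares[2]) +
    pair_loglik(pair_suffstats(dz), 0, 1, shares[1] / 2 + shares[2])
}

#' ACE decomposition across all CpGs of a methylation matrix
#'
#' Extracts complete MZ and DZ twin pairs from the pedigree and runs
#' [fit_ace()] per CpG.
#'
#' @param meth A residual-stage [meth_matrix()] adjusted without family or
#'   zygosity terms.
#' @param pedigree Pedigree tibble (`sample_id`, `family_id`, `zygosity`).
#' @return Tibble of per-CpG estimates, class `ace_scan`.
#' @export
ace_scan <- function(meth, pedigree) {
  stopifnot(inherits(meth, "meth_matrix"))
  ped <- pedigree[match(meth$samples$sample_id, pedigree$sample_id), ]
  pair_rows <- function(zyg) {
    idx <- which(ped$zygosity == zyg)
    sp <- split(idx, ped$family_id[idx])
    sp <- sp[lengths(sp) == 2]
    do.call(rbind, sp)
  }
  mz <- pair_rows("MZ")
  dz <- pair_rows("DZ")
  if (is.null(mz) || is.null(dz) || nrow(mz) < 10 || nrow(dz) < 10) {
    abort("need at least 10 complete pairs of each zygosity")
  }
  out <- purrr::map_dfr(seq_len(ncol(meth$values)), function(j) {
    y <- meth$values[, j]
    fit_ace(cbind(y[mz[, 1]], y[mz[, 2]]),
            cbind(y[dz[, 1]], y[dz[, 2]]),
            cpg_id = meth$cpgs$cpg_id[j])
  })
  class(out) <- c("ace_scan", class(out))
  out
}

#' Stratified summaries of heritability estimates
#'
#' Summarises per-CpG ACE shares by annotation category and (optionally) by
#' a variability stratum defined by the raw beta-value standard deviation:
#' mean, sd, median, IQR and 95% CI of the mean of `A`, plus the
#' zero-inflation rate (share of CpGs with `A < 0.01`).
#'
#' @param estimates An [ace_scan()] result (or compatible tibble).
#' @param annotations Tibble `cpg_id`, `category` mapping CpGs to annotation
#'   categories; CpGs in `estimates` without a category are summarised under
#'   `"unannotated"`. Category ids absent from `estimates` are listed in the
#'   `unknown_categories` attribute rather than dropped silently.
#' @param variability Optional tibble `cpg_id`, `sd` of raw beta-values.
#' @param sd_threshold Variability cut defining the "variable CpG" stratum.
#' @return Tibble of per-stratum summaries.
#' @export
summarize_heritability <- function(estimates, annotations = NULL,
                                   variability = NULL, sd_threshold = 0.025) {
  est <- filter(as_tibble(estimates), .data$converged)
  if (nrow(est) == 0) abort("no converged estimates to summarise")
  unknown <- character(0)
  if (!is.null(annotations)) {
    unknown <- setdiff(annotations$cpg_id, est$cpg_id)
    est <- left_join(est, annotations, by = "cpg_id") |>
      mutate(category = dplyr::coalesce(.data$category, "unannotated"))
  } else {
    est$category <- "all"
  }
  if (!is.null(variability)) {
    est <- left_join(est, variability, by = "cpg_id") |>
      mutate(variable = ifelse(.data$sd > sd_threshold,
                               sprintf("sd > %g", sd_threshold),
                               sprintf("sd <= %g", sd_threshold)))
  } else {
    est$variable <- "all"
  }
  out <- est |>
    group_by(.data$category, .data$variable) |>
    summarise(n = n(),
              mean_A = mean(.data$A), sd_A = sd(.data$A),
              median_A = median(.data$A),
              iqr_A = stats::IQR(.data$A),
              ci_lo = mean(.data$A) - 1.96 * sd(.data$A) / sqrt(n()),
              ci_hi = mean(.data$A) + 1.96 * sd(.data$A) / sqrt(n()),
              zero_inflation = mean(.data$A < 0.01),
              .groups = "drop")
  attr(out, "unknown_categories") <- unknown
  out
}
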