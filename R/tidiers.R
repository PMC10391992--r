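#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation FDR curve
#' @param x An `fdr_curve`.
#' @param ... Unused.
#' @return The threshold grid as a tibble.
#' @exportS3Method generics::tidy
tidy.fdr_curve <- function(x, ...) x$curve

#' One-row summary of a permutation FDR curve
#' @param x An `fdr_curve`.
#' @param ... Unused.
#' @return Tibble with the selected threshold, target, B, and the number of
#'   significant pairs.
#' @exportS3Method generics::glance
glance.fdr_curve <- function(x, ...) {
  n_sig <- if (is.na(x$selected_threshold)) 0L else
    x$curve$n_obs[match(x$selected_threshold, x$curve$threshold)]
  tibble(selected_threshold = x$selected_threshold, target = x$target,
         B = x$B, n_significant = n_sig)
}

#' Tidy the heritability-on-meQTL-status regression
#' @param x A `herit_meqtl_reg`.
#' @param ... Unused.
#' @return Coefficient table as a tibble.
#' @exportS3Method generics::tidy
tidy.herit_meqtl_reg <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
         statistic = cf[, 3], p_value = cf[, 4])
}

#' One-row summary of the heritability-on-meQTL-status regression
#' @param x A `herit_meqtl_reg`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `f_statistic`, degrees of freedom, `p`.
#' @exportS3Method generics::glance
glance.herit_meqtl_reg <- function(x, ...) {
  tibble(r_squared = x$r_squared, f_statistic = x$f_statistic,
         df1 = x$df[1], df2 = x$df[2], p = x$p)
}

#' Tidy a discovery result
#' @param x A `meqtl_discovery`.
#' @param ... Unused.
#' @return The significant pair tibble.
#' @exportS3Method generics::tidy
tidy.meqtl_discovery <- function(x, ...) x$significant

#' One-row summary of a discovery result
#' @param x A `meqtl_discovery`.
#' @param ... Unused.
#' @return Tibble of pair counts and selected thresholds.
#' @exportS3Method generics::glance
glance.meqtl_discovery <- function(x, ...) {
  tibble(n_pairs = nrow(x$meta),
         n_significant = nrow(x$significant),
         n_cis = sum(x$significant$type == "cis"),
         n_trans = sum(x$significant$type == "trans"),
         threshold_cis = unname(x$thresholds["cis"]),
         threshold_trans = unname(x$thresholds["trans"]))
}

#' Plot a permutation FDR curve
#'
#' Estimated FDR against the candidate p-value threshold (log scale) with
#' the target level and selected threshold marked.
#'
#' @param object An `fdr_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fdr_curve <- function(object, ...) {
  df <- object$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                        y = .data$fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$target, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "meta-analysis p-value threshold",
                  y = "estimated FDR",
                  title = sprintf("Permutation FDR (B = %d)", object$B)) +
    ggplot2::theme_minimal()
  if (!is.na(object$selected_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_threshold,
                                 colour = "red", linetype = "dotted")
  }
  p
}

#' Plot ACE shares across CpGs
#'
#' Stacked cumulative shares of additive-genetic, shared- and
#' unique-environment variance, CpGs ordered by heritability.
#'
#' @param object An `ace_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ace_scan <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$converged) |>
    arrange(.data$A) |>
    mutate(rank = row_number()) |>
    tidyr::pivot_longer(c("A", "C", "E"), names_to = "component",
                        values_to = "share")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$share,
                                   fill = .data$component)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "CpG (ordered by heritability)",
                  y = "share of variance",
                  fill = "ACE component") +
    ggplot2::theme_minimal()
}

#' Forest plot of enrichment odds ratios
#'
#' @param object Enrichment tibble with `annotation`, `or`, `ci_lo`,
#'   `ci_hi` (e.g. from [enrichment_test()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$or, y = .data$annotation)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of SNP-CpG distances for significant cis pairs
#'
#' @param significant Significant pair tibble with `snp_id`, `cpg_id`.
#' @param geno A [geno_matrix()] (for SNP positions).
#' @param cpgs Tibble `cpg_id`, `chrom`, `pos`.
#' @return A ggplot.
#' @export
plot_meqtl_distance <- function(significant, geno, cpgs) {
  df <- significant |>
    filter(.data$type == "cis") |>
    left_join(geno$snps[, c("snp_id", "pos")], by = "snp_id") |>
    left_join(cpgs[, c("cpg_id", "pos")], by = "cpg_id",
              suffix = c("_snp", "_cpg")) |>
    mutate(distance = .data$pos_snp - .data$pos_cpg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance / 1e3)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::labs(x = "SNP - CpG distance (kbp)", y = "cis pairs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
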