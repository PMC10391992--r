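#' Pairwise LD between two SNPs as squared dosage correlation
#'
#' Computed over the pooled (all-cohort) samples, pairwise-complete.
#'
#' @param geno A [geno_matrix()].
#' @param snp_i,snp_j SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(geno, snp_i, snp_j) {
  i <- match(snp_i, geno$snps$snp_id)
  j <- match(snp_j, geno$snps$snp_id)
  if (is.na(i) || is.na(j)) abort("unknown SNP id")
  x <- geno$dosages[, i]
  y <- geno$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    abort("monomorphic SNP: LD undefined")
  }
  cor(x[ok], y[ok])^2
}

#' Pairwise LD matrix for a set of SNPs
#'
#' @param geno A [geno_matrix()].
#' @param snp_ids SNP ids (default: all).
#' @param signed If `TRUE`, return the signed dosage correlation matrix
#'   instead of r-squared.
#' @return Square matrix with SNP ids as dimnames.
#' @export
ld_matrix <- function(geno, snp_ids = NULL, signed = FALSE) {
  snp_ids <- snp_ids %||% geno$snps$snp_id
  idx <- match(snp_ids, geno$snps$snp_id)
  if (anyNA(idx)) abort("unknown SNP id in snp_ids")
  r <- suppressWarnings(cor(geno$dosages[, idx, drop = FALSE],
                            use = "pairwise.complete.obs"))
  dimnames(r) <- list(snp_ids, snp_ids)
  if (signed) r else r^2
}

#' Greedy LD clumping of meQTL SNPs
#'
#' Sorts SNPs by their number of associated CpGs (descending; ties broken by
#' the p-value of their best association, then by position), repeatedly
#' takes the top unclumped SNP as the representative of a new region, and
#' absorbs all unclumped SNPs on the same chromosome within `window` bp of
#' the representative with `r^2 > r2_min`. Cis- and trans-meQTL sets should
#' be clumped separately (call once per type).
#'
#' @param snp_stats Tibble with `snp_id`, `chrom`, `pos`, `n_cpgs`
#'   (associated-CpG count) and `best_p` (p of the SNP's best association).
#' @param ld Square r-squared matrix covering the SNPs (e.g. from
#'   [ld_matrix()]).
#' @param r2_min LD threshold; SNPs join a region when r-squared is
#'   strictly greater than this.
#' @param window Absorb SNPs within this many bp of the representative
#'   (interpreted as +/- `window`).
#' @return Tibble: `region_id`, `snp_id`, `representative` (logical),
#'   `rep_snp_id`, `chrom`, with one row per input SNP.
#' @export
clump <- function(snp_stats, ld, r2_min = 0.1, window = 2e6) {
  stopifnot(all(c("snp_id", "chrom", "pos", "n_cpgs") %in%
                  names(snp_stats)))
  if (!"best_p" %in% names(snp_stats)) snp_stats$best_p <- NA_real_
  ss <- arrange(snp_stats, dplyr::desc(.data$n_cpgs), .data$best_p,
                .data$pos)
  ld <- ld[ss$snp_id, ss$snp_id, drop = FALSE]
  n <- nrow(ss)
  assigned <- integer(n)        # 0 = unclumped
  rep_of <- integer(0)
  region <- 0L
  for (i in seq_len(n)) {
    if (assigned[i] != 0L) next
    region <- region + 1L
    assigned[i] <- region
    rep_of[region] <- i
    free <- which(assigned == 0L)
    if (length(free)) {
      hit <- free[ss$chrom[free] == ss$chrom[i] &
                    abs(ss$pos[free] - ss$pos[i]) <= window &
                    ld[free, i] > r2_min]
      assigned[hit] <- region
    }
  }
  tibble(region_id = sprintf("clump%04d", assigned),
         snp_id = ss$snp_id,
         representative = seq_len(n) %in% rep_of,
         rep_snp_id = ss$snp_id[rep_of[assigned]],
         chrom = ss$chrom)
}

#' Per-CpG effective meQTL counts after clumping
#'
#' Counts, per CpG and association type, the number of distinct clump
#' regions containing at least one of its associated SNPs; within each
#' region the CpG's most significant SNP is recorded as its representative.
#' Also tallies, per region, the number of distinct associated CpGs.
#'
#' @param pairs Significant pair tibble (`snp_id`, `cpg_id`, `type`, `p`).
#' @param clumps Output of [clump()] covering all SNPs in `pairs`.
#' @return List: `cpg_counts` (tibble `cpg_id`, `type`, `n_regions`),
#'   `cpg_region_top` (per CpG x region most significant SNP),
#'   `region_counts` (tibble `region_id`, `type`, `n_cpgs`).
#' @export
per_cpg_clumped_counts <- function(pairs, clumps) {
  unknown <- setdiff(pairs$snp_id, clumps$snp_id)
  if (length(unknown)) {
    abort(sprintf("pairs reference SNPs missing from clumps: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  # cis and trans SNP sets are clumped separately: join on type when the
  # clump table distinguishes it
  if ("type" %in% names(clumps)) {
    joined <- left_join(pairs, clumps[, c("snp_id", "type", "region_id")],
                        by = c("snp_id", "type"))
    if (anyNA(joined$region_id)) {
      abort("pairs reference SNP/type combinations missing from clumps")
    }
  } else {
    joined <- left_join(pairs, clumps[, c("snp_id", "region_id")],
                        by = "snp_id")
  }
  cpg_region_top <- joined |>
    group_by(.data$cpg_id, .data$type, .data$region_id) |>
    arrange(.data$p) |>
    slice(1) |>
    ungroup() |>
    select("cpg_id", "type", "region_id", top_snp_id = "snp_id",
           top_p = "p")
  cpg_counts <- cpg_region_top |>
    count(.data$cpg_id, .data$type, name = "n_regions")
  region_counts <- joined |>
    group_by(.data$region_id, .data$type) |>
    summarise(n_cpgs = dplyr::n_distinct(.data$cpg_id), .groups = "drop")
  list(cpg_counts = cpg_counts, cpg_region_top = cpg_region_top,
       region_counts = region_counts)
}

#' Outlier threshold for connectivity counts: Q3 + 3 IQR
#'
#' Quartiles use linear interpolation between order statistics (R's default
#' type-7 convention); entities with counts strictly greater than the
#' threshold are flagged.
#'
#' @param counts Numeric vector (>= 4 values).
#' @return List: `q3`, `iqr`, `threshold`, `flagged` (logical vector).
#' @export
outlier_threshold <- function(counts) {
  if (length(counts) < 4) abort("need at least 4 values")
  q <- quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  thr <- q[2] + 3 * (q[2] - q[1])
  list(q3 = q[2], iqr = q[2] - q[1], threshold = thr,
       flagged = counts > thr)
}

#' Connectivity statistics with highly-regulated / key-region flags
#'
#' Applies [outlier_threshold()] to the per-CpG clumped meQTL counts
#' ("highly regulated" CpGs) and to the per-region associated-CpG counts
#' ("key regulatory regions"), separately per association type.
#'
#' @param pairs,clumps As in [per_cpg_clumped_counts()].
#' @return List of class `connectivity_stats`: `cpg` and `region` tibbles
#'   with counts and `flagged`, plus `thresholds` (per type and side).
#' @export
connectivity_stats <- function(pairs, clumps) {
  cc <- per_cpg_clumped_counts(pairs, clumps)
  flag_by_type <- function(df, count_col) {
    df |>
      group_by(.data$type) |>
      mutate(flagged = if (n() >= 4)
        outlier_threshold(.data[[count_col]])$flagged else FALSE) |>
      ungroup()
  }
  thr_by_type <- function(df, count_col) {
    df |>
      group_by(.data$type) |>
      summarise(q3 = if (n() >= 4)
        outlier_threshold(.data[[count_col]])$q3 else NA_real_,
        iqr = if (n() >= 4)
          outlier_threshold(.data[[count_col]])$iqr else NA_real_,
        threshold = if (n() >= 4)
          outlier_threshold(.data[[count_col]])$threshold else NA_real_,
        .groups = "drop")
  }
  out <- list(
    cpg = flag_by_type(cc$cpg_counts, "n_regions"),
    region = flag_by_type(cc$region_counts, "n_cpgs"),
    thresholds = bind_rows(
      mutate(thr_by_type(cc$cpg_counts, "n_regions"), side = "cpg"),
      mutate(thr_by_type(cc$region_counts, "n_cpgs"), side = "region")),
    cpg_region_top = cc$cpg_region_top)
  class(out) <- "connectivity_stats"
  out
}

#' @export
print.connectivity_stats <- function(x, ...) {
  cat("<connectivity_stats>\n")
  cat(sprintf("  highly regulated CpGs: %d of %d\n",
              sum(x$cpg$flagged), nrow(x$cpg)))
  cat(sprintf("  key regulatory regions: %d of %d\n",
              sum(x$region$flagged), nrow(x$region)))
  invisible(x)
}
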