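#' Two-stage multi-cohort meQTL discovery with permutation FDR
#'
#' Runs the full discovery engine on residualised per-cohort data: liberal
#' per-cohort candidate scans, DerSimonian-Laird random-effects
#' meta-analysis, B family-preserving permutations re-running the identical
#' scan + meta + consistency pipeline to build the null p-value sets,
#' per-type permutation-FDR threshold selection, and the two-or-more-cohorts
#' same-direction consistency filter.
#'
#' @param cohorts Named list, one entry per cohort, each a list with `geno`
#'   (a [geno_matrix()]) and `meth` (a residual-stage [meth_matrix()] with
#'   the same samples).
#' @param pedigrees Optional named list of pedigree tibbles (per cohort)
#'   used by the family-preserving permutation.
#' @param p_cis,p_trans Candidate thresholds.
#' @param window cis window (bp).
#' @param B Number of permutations.
#' @param fdr_target FDR target.
#' @param seed Integer seed for the permutations.
#' @return List of class `meqtl_discovery`: `significant` (final pair
#'   tibble with `significant` flag already applied), `meta` (all
#'   consistency-filtered meta results), `fdr` (named list of
#'   [permutation_fdr()] curves per type), `thresholds` (named numeric),
#'   `candidates` (per-cohort record counts).
#' @export
meqtl_discovery <- function(cohorts, pedigrees = NULL, p_cis = 5e-3,
                            p_trans = 5e-6, window = 1e6, B = 20,
                            fdr_target = 0.05, seed = 1) {
  scan_all <- function(meth_list) {
    bind_rows(purrr::imap(meth_list, function(me, nm) {
      scan_cohort(cohorts[[nm]]$geno, me, p_cis = p_cis, p_trans = p_trans,
                  window = window, cohort = nm)
    }))
  }
  meth_obs <- purrr::map(cohorts, "meth")
  names(meth_obs) <- names(cohorts)
  obs_records <- scan_all(meth_obs)
  obs_meta <- consistency_filter(meta_analyse(obs_records))

  null_p <- list(cis = vector("list", B), trans = vector("list", B))
  for (b in seq_len(B)) {
    meth_perm <- purrr::imap(meth_obs, function(me, nm) {
      permute_cohort(me, pedigrees[[nm]],
                     seed = child_seed(seed, paste0("perm", b, nm)))
    })
    pm <- consistency_filter(meta_analyse(scan_all(meth_perm)))
    null_p$cis[[b]] <- pm$p[pm$type == "cis"]
    null_p$trans[[b]] <- pm$p[pm$type == "trans"]
  }
  fdr <- list(
    cis = permutation_fdr(obs_meta$p[obs_meta$type == "cis"],
                          null_p$cis, target = fdr_target),
    trans = permutation_fdr(obs_meta$p[obs_meta$type == "trans"],
                            null_p$trans, target = fdr_target))
  thr <- c(cis = fdr$cis$selected_threshold,
           trans = fdr$trans$selected_threshold)
  sig <- obs_meta |>
    mutate(significant = (.data$type == "cis" & !is.na(thr["cis"]) &
                            .data$p <= thr["cis"]) |
             (.data$type == "trans" & !is.na(thr["trans"]) &
                .data$p <= thr["trans"])) |>
    filter(.data$significant)
  out <- list(significant = sig, meta = obs_meta, fdr = fdr,
              thresholds = thr,
              candidates = count(obs_records, .data$cohort, .data$type))
  class(out) <- "meqtl_discovery"
  out
}

#' @export
print.meqtl_discovery <- function(x, ...) {
  cat("<meqtl_discovery>\n")
  cat(sprintf("  consistency-filtered pairs: %d\n", nrow(x$meta)))
  cat(sprintf("  significant pairs: %d (cis %d, trans %d)\n",
              nrow(x$significant), sum(x$significant$type == "cis"),
              sum(x$significant$type == "trans")))
  cat(sprintf("  thresholds: cis %.3g, trans %.3g\n",
              x$thresholds["cis"], x$thresholds["trans"]))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic study (simulated
#'   inputs; reading external files instead is done by constructing the
#'   cohort list manually and calling [meqtl_discovery()]).
#' @param p_cis,p_trans Candidate thresholds.
#' @param window cis window (bp).
#' @param permutations Number of permutations B.
#' @param fdr_target FDR target.
#' @param clump_r2,clump_window LD clumping parameters.
#' @param run_heritability Fit the twin ACE model (needs twin pairs in
#'   cohort 1).
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), p_cis = 5e-3,
                            p_trans = 5e-6, window = 1e6,
                            permutations = 20, fdr_target = 0.05,
                            clump_r2 = 0.1, clump_window = 2e6,
                            run_heritability = TRUE, seed = 1) {
  structure(list(sim = sim, p_cis = p_cis, p_trans = p_trans,
                 window = window, permutations = permutations,
                 fdr_target = fdr_target, clump_r2 = clump_r2,
                 clump_window = clump_window,
                 run_heritability = run_heritability,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end synthetic meQTL pipeline
#'
#' Simulates the multi-cohort study, applies genotype and probe QC, INT and
#' covariate residualisation, runs the discovery engine
#' ([meqtl_discovery()]), LD-clumps the significant meQTLs with connectivity
#' outlier calling, and (optionally) fits the twin ACE model and the
#' heritability-on-meQTL-status regression. When `out_dir` is given, each
#' stage's table is written as TSV together with a JSON manifest (stage,
#' file, md5, parameters, seed); reruns with the same config reproduce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `meqtl_pipeline`: `truth`, `discovery`,
#'   `clumps`, `connectivity`, `ace`, `herit_reg`, `log` (tibble of stage
#'   messages).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- tibble(stage = stage, message = msg)
  }
  sim <- config$sim

  g <- simulate_genotypes(sim)
  cpg_pos <- simulate_cpg_positions(sim)
  truth <- plant_effects(g$geno, cpg_pos, sim)
  mm <- simulate_methylation(g$geno, truth, g$pedigree, sim, cpg_pos)
  note("simulate", sprintf("%d samples, %d SNPs, %d CpGs, %d planted effects",
                           nrow(g$geno$dosages), ncol(g$geno$dosages),
                           ncol(mm$meth$values), nrow(truth)))

  cohorts <- list()
  pedigrees <- list()
  for (co in unique(g$pedigree$cohort)) {
    rows <- g$pedigree$cohort == co
    geno_c <- subset_geno_samples(g$geno, rows)
    qc <- filter_genotypes(geno_c)
    meth_c <- subset_meth(mm$meth, keep_samples = rows)
    pq <- filter_probes(meth_c)
    covars_c <- mm$covars[rows, , drop = FALSE]
    # keep genotype and methylation samples aligned after QC drops
    common <- intersect(qc$geno$samples$sample_id,
                        pq$meth$samples$sample_id)
    geno_c <- subset_geno_samples(
      qc$geno, match(common, qc$geno$samples$sample_id))
    meth_kept <- subset_meth(
      pq$meth, keep_samples = match(common, pq$meth$samples$sample_id))
    meth_res <- adjust_methylation(
      int_transform(meth_kept), covars_c,
      fixed = c("sex", "age", "smoking", "cd4t", "mono"),
      grouping = c("plate", "chip_pos"))
    cohorts[[co]] <- list(geno = geno_c, meth = meth_res)
    pedigrees[[co]] <- g$pedigree[rows, , drop = FALSE]
    note("qc", sprintf("%s: %d SNPs kept, %d probes kept", co,
                       ncol(qc$geno$dosages), ncol(pq$meth$values)))
  }

  disc <- meqtl_discovery(cohorts, pedigrees, p_cis = config$p_cis,
                          p_trans = config$p_trans, window = config$window,
                          B = config$permutations,
                          fdr_target = config$fdr_target,
                          seed = config$seed)
  note("discovery", sprintf("%d significant pairs", nrow(disc$significant)))

  clumps <- NULL; conn <- NULL
  if (nrow(disc$significant) > 0) {
    pooled <- g$geno
    snp_stats <- disc$significant |>
      group_by(.data$snp_id, .data$type) |>
      summarise(n_cpgs = dplyr::n_distinct(.data$cpg_id),
                best_p = min(.data$p), .groups = "drop") |>
      left_join(pooled$snps[, c("snp_id", "chrom", "pos")], by = "snp_id")
    clumps <- bind_rows(lapply(split(snp_stats, snp_stats$type),
                               function(st) {
      ld <- ld_matrix(pooled, st$snp_id)
      mutate(clump(st, ld, r2_min = config$clump_r2,
                   window = config$clump_window), type = st$type[1])
    }))
    conn <- connectivity_stats(disc$significant, clumps)
    note("clump", sprintf("%d clump regions",
                          dplyr::n_distinct(clumps$region_id)))
  }

  ace <- NULL; herit_reg <- NULL
  if (isTRUE(config$run_heritability) &&
      sum(g$pedigree$zygosity == "MZ") >= 20 &&
      sum(g$pedigree$zygosity == "DZ") >= 20) {
    co1 <- unique(g$pedigree$cohort)[1]
    rows <- g$pedigree$cohort == co1
    meth_c <- subset_meth(mm$meth, keep_samples = rows)
    covars_c <- mm$covars[rows, , drop = FALSE]
    # per Methods: residuals without family/zygosity correction
    meth_res <- adjust_methylation(
      int_transform(meth_c), covars_c,
      fixed = c("sex", "age", "smoking", "cd4t", "mono"),
      grouping = c("plate", "chip_pos"))
    ace <- ace_scan(meth_res, pedigrees[[co1]])
    if (nrow(disc$significant) > 0) {
      status <- tibble(cpg_id = mm$meth$cpgs$cpg_id) |>
        mutate(has_cis = .data$cpg_id %in%
                 disc$significant$cpg_id[disc$significant$type == "cis"],
               has_trans = .data$cpg_id %in%
                 disc$significant$cpg_id[disc$significant$type == "trans"])
      herit_reg <- tryCatch(heritability_meqtl_regression(ace, status),
                            error = function(e) NULL)
    }
    note("heritability", sprintf("%d CpGs fitted, %d converged",
                                 nrow(ace), sum(ace$converged)))
  } else {
    note("heritability", "skipped (pedigree lacks enough twin pairs)")
  }

  out <- list(truth = truth, discovery = disc, clumps = clumps,
              connectivity = conn, ace = ace, herit_reg = herit_reg,
              log = bind_rows(log), config = config)
  class(out) <- "meqtl_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  emit <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return()
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path, progress = FALSE)
    files[[name]] <<- path
  }
  emit(result$truth, "truth")
  emit(result$discovery$significant, "significant_pairs")
  emit(result$discovery$meta, "meta_results")
  emit(result$discovery$fdr$cis$curve, "fdr_curve_cis")
  emit(result$discovery$fdr$trans$curve, "fdr_curve_trans")
  emit(result$clumps, "clumps")
  if (!is.null(result$connectivity)) {
    emit(result$connectivity$cpg, "connectivity_cpg")
    emit(result$connectivity$region, "connectivity_region")
  }
  if (!is.null(result$ace)) emit(result$ace, "ace_estimates")
  emit(result$log, "run_log")
  manifest <- list(
    seed = result$config$seed,
    parameters = result$config[c("p_cis", "p_trans", "window",
                                 "permutations", "fdr_target", "clump_r2",
                                 "clump_window")],
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.meqtl_pipeline <- function(x, ...) {
  cat("<meqtl_pipeline>\n")
  print(x$discovery)
  if (!is.null(x$ace)) {
    cat(sprintf("  mean heritability (A): %.3f over %d converged CpGs\n",
                mean(x$ace$A[x$ace$converged]), sum(x$ace$converged)))
  }
  invisible(x)
}

#' False-discovery proportion of a discovery result against planted truth
#'
#' A reported pair counts as a true discovery when its SNP is a planted SNP
#' for that type, or is in LD (`r^2 >` `r2_tag`) with one, computed on the
#' pooled samples; all other reported pairs are false.
#'
#' @param significant Significant pair tibble (`snp_id`, `type`).
#' @param truth Truth table from [plant_effects()].
#' @param geno Pooled [geno_matrix()] for the LD tagging.
#' @param type Association type to evaluate (`"cis"` by default).
#' @param r2_tag LD threshold for counting a tagging SNP as true.
#' @return List: `fdp`, `n_reported`, `n_false`.
#' @export
false_discovery_proportion <- function(significant, truth, geno,
                                       type = "cis", r2_tag = 0.1) {
  rep_pairs <- filter(significant, .data$type == !!type)
  if (nrow(rep_pairs) == 0) {
    return(list(fdp = NA_real_, n_reported = 0L, n_false = 0L))
  }
  planted <- unique(truth$snp_id[truth$type == type])
  rep_snps <- unique(rep_pairs$snp_id)
  extra <- setdiff(rep_snps, planted)
  tagged <- character(0)
  if (length(extra) && length(planted)) {
    r <- suppressWarnings(
      cor(geno$dosages[, extra, drop = FALSE],
          geno$dosages[, planted, drop = FALSE],
          use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    tagged <- extra[apply(r^2 > r2_tag, 1, any)]
  }
  true_snps <- c(planted, tagged)
  false <- !(rep_pairs$snp_id %in% true_snps)
  list(fdp = mean(false), n_reported = nrow(rep_pairs),
       n_false = sum(false))
}
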