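#' Read a BED annotation track
#'
#' BED is 0-based half-open; intervals are kept in that convention and
#' converted only at the overlap boundary. Intervals are sorted within
#' chromosome on load.
#'
#' @param path Path to a 3+ column BED file (optional 4th column becomes
#'   the category label).
#' @param name Track name.
#' @return Tibble of class `annotation_track`: `chrom`, `start`, `end`,
#'   `category`, with attribute `name`.
#' @export
read_bed <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  annotation_track(df[[1]], df[[2]], df[[3]],
                   category = if (ncol(df) >= 4) df[[4]] else name,
                   name = name)
}

#' Construct an annotation track from interval vectors
#'
#' @param chrom,start,end Interval coordinates, 0-based half-open (BED).
#' @param category Optional per-interval category labels.
#' @param name Track name.
#' @return Tibble of class `annotation_track`.
#' @export
annotation_track <- function(chrom, start, end, category = name,
                             name = "track") {
  if (any(start >= end)) abort("intervals must satisfy start < end")
  out <- tibble(chrom = as.character(chrom), start = as.numeric(start),
                end = as.numeric(end),
                category = rep_len(as.character(category), length(chrom))) |>
    arrange(.data$chrom, .data$start, .data$end)
  attr(out, "name") <- name
  class(out) <- c("annotation_track", class(out))
  out
}

#' The MHC region (GRCh37) as an annotation track
#'
#' Chromosome 6, base-pair positions 28,477,797 to 33,448,354 (1-based
#' inclusive), stored in BED convention.
#'
#' @return An [annotation_track()].
#' @export
mhc_track <- function() {
  annotation_track("6", 28477796, 33448354, category = "MHC", name = "MHC")
}

track_granges <- function(track) {
  # BED half-open [start, end) -> 1-based inclusive [start+1, end]
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1, track$end))
}

#' Map 1-based point positions onto a BED annotation track
#'
#' A point at 1-based position p lies in interval \[start, end) iff
#' `start <= p - 1 < end`. Points on chromosomes absent from the track are
#' non-members and counted in the `unknown_chrom` attribute.
#'
#' @param points Tibble with `chrom`, `pos` (1-based).
#' @param track An [annotation_track()].
#' @return Logical membership vector with attribute `unknown_chrom`.
#' @export
map_to_annotations <- function(points, track) {
  pts <- GenomicRanges::GRanges(as.character(points$chrom),
                                IRanges::IRanges(points$pos, points$pos))
  member <- suppressWarnings(
    IRanges::overlapsAny(pts, track_granges(track)))
  unk <- sum(!(as.character(points$chrom) %in% unique(track$chrom)))
  attr(member, "unknown_chrom") <- unk
  member
}

#' Two-tailed Fisher exact test with Haldane-Anscombe odds ratio
#'
#' The exact two-sided p-value sums, over all tables with the observed
#' margins, the hypergeometric probabilities not exceeding that of the
#' observed table (point-probability ordering). The odds ratio is `ad/bc`
#' with 0.5 added to every cell when any cell is zero, and the confidence
#' interval is the Woolf logit interval on the (possibly corrected) cells.
#'
#' @param a,b,c_,d 2x2 counts; `a + b` is the interest-set size and
#'   `a`, `c_` are the in-annotation counts of interest and background.
#' @param conf_level Confidence level for the Woolf interval.
#' @return One-row tibble: `a`, `b`, `c`, `d`, `or`, `ci_lo`, `ci_hi`, `p`.
#' @export
fisher_two_tailed <- function(a, b, c_, d, conf_level = 0.95) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0)) abort("counts must be non-negative")
  if (a + b == 0 || c_ + d == 0) abort("both rows must be non-empty")
  if (sum(cells) == 0) abort("grand total must be positive")
  m <- a + b       # interest row
  nn <- c_ + d     # background row
  k <- a + c_      # annotation column
  lo <- max(0, k - nn)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(sum(1 / cells))
  tibble(a = a, b = b, c = c_, d = d, or = or,
         ci_lo = exp(log(or) - z * se_log),
         ci_hi = exp(log(or) + z * se_log), p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to the input order (a thin wrapper over
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Annotation enrichment of an interest set against a background
#'
#' Builds the 2x2 table (interest/background x in/out of annotation) and
#' applies [fisher_two_tailed()], one row per track category.
#'
#' @param interest,background Tibbles with `chrom`, `pos`.
#' @param track An [annotation_track()].
#' @return Tibble with one row per category: counts, OR, CI, `p`, `q`
#'   (BH-adjusted across categories), `method = "exact"`.
#' @export
enrichment_test <- function(interest, background, track) {
  cats <- unique(track$category)
  res <- purrr::map_dfr(cats, function(cc) {
    sub <- track[track$category == cc, , drop = FALSE]
    mi <- map_to_annotations(interest, sub)
    mb <- map_to_annotations(background, sub)
    ft <- fisher_two_tailed(sum(mi), sum(!mi), sum(mb), sum(!mb))
    mutate(ft, annotation = cc, .before = 1)
  })
  res$q <- bh_adjust(res$p)
  res$method <- "exact"
  res
}

#' MAF- and distance-matched resampled enrichment background
#'
#' For each of `B` iterations, draws a background set of the interest set's
#' size with the interest set's (MAF bin x distance bin) category
#' composition — sampling without replacement within each category and with
#' replacement across categories — and computes the odds ratio of
#' interest-set annotation membership against that background (cells
#' corrected by +0.5 when needed). The point estimate is the mean OR over
#' iterations and the CI the 2.5%/97.5% percentiles of the resampling
#' distribution.
#'
#' @param interest_snps,universe_snps Tibbles with `snp_id`, `chrom`, `pos`,
#'   `maf`, `dist_to_cpg` (distance to the nearest target CpG in bp).
#' @param track An [annotation_track()] (single category).
#' @param maf_bins Breaks for MAF bins (default width 0.05 over (0, 0.5\]).
#' @param distance_bins Breaks for distance bins (default log10-spaced
#'   0-1k, 1k-10k, 10k-100k, 100k-1M, >1M).
#' @param B Number of resampling iterations.
#' @param seed Integer seed.
#' @return One-row tibble: `or` (mean), `ci_lo`, `ci_hi`, `B`,
#'   `method = "resampled"`, with attribute `or_samples`.
#' @export
matched_background_resample <- function(interest_snps, universe_snps, track,
                                        maf_bins = seq(0, 0.5, by = 0.05),
                                        distance_bins = c(0, 1e3, 1e4, 1e5,
                                                          1e6, Inf),
                                        B = 1000, seed = 1) {
  bin_of <- function(df) {
    paste(cut(df$maf, maf_bins, include.lowest = TRUE),
          cut(df$dist_to_cpg, distance_bins, include.lowest = TRUE))
  }
  int_bin <- bin_of(interest_snps)
  uni_bin <- bin_of(universe_snps)
  comp <- table(int_bin)
  missing_cat <- setdiff(names(comp), unique(uni_bin))
  if (length(missing_cat)) {
    abort(sprintf("universe has no SNPs in matched categories: %s",
                  paste(missing_cat, collapse = "; ")))
  }
  uni_by_cat <- split(seq_len(nrow(universe_snps)), uni_bin)
  member_int <- map_to_annotations(interest_snps, track)
  member_uni <- map_to_annotations(universe_snps, track)
  a <- sum(member_int); b <- sum(!member_int)
  ors <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(bb) {
      bg <- unlist(lapply(names(comp), function(cat) {
        pool <- uni_by_cat[[cat]]
        nk <- comp[[cat]]
        pool[sample.int(length(pool), nk,
                        replace = length(pool) < nk)]
      }), use.names = FALSE)
      cc <- sum(member_uni[bg]); dd <- length(bg) - cc
      cells <- c(a, b, cc, dd)
      if (any(cells == 0)) cells <- cells + 0.5
      (cells[1] * cells[4]) / (cells[2] * cells[3])
    }, numeric(1))
  })
  out <- tibble(or = mean(ors),
                ci_lo = quantile(ors, 0.025, names = FALSE),
                ci_hi = quantile(ors, 0.975, names = FALSE),
                B = B, method = "resampled")
  attr(out, "or_samples") <- ors
  out
}

#' Share of SNP-CpG pairs falling inside one common TAD
#'
#' For each pair, membership requires both the CpG and the SNP position to
#' lie within the same topologically associating domain interval;
#' cross-chromosome pairs count as not-same-TAD and are tallied. The sizes
#' of the TADs containing intra-chromosomal pairs are collected and the
#' cis/trans size difference tested by a Welch two-sided t-test.
#'
#' @param pairs Tibble with `cpg_chrom`, `cpg_pos`, `snp_chrom`, `snp_pos`,
#'   `type`.
#' @param tads An [annotation_track()] of TAD intervals. Unsorted or
#'   overlapping input is normalised (sorted, overlaps merged) with a
#'   warning.
#' @return List: `share` (overall fraction same-TAD), `by_type` tibble,
#'   `n_cross_chrom`, `tad_size_test` (htest or NULL), `tad_sizes` tibble.
#' @export
tad_overlap <- function(pairs, tads) {
  gr <- track_granges(tads)
  # merge genuinely overlapping intervals only; adjacent TADs stay distinct
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  if (length(red) != length(gr)) {
    warn("overlapping TAD intervals merged before overlap computation")
    gr <- red
  }
  gr <- GenomicRanges::sort(gr)
  find_tad <- function(chrom, pos) {
    pts <- GenomicRanges::GRanges(as.character(chrom),
                                  IRanges::IRanges(pos, pos))
    ov <- GenomicRanges::findOverlaps(pts, gr, select = "first")
    as.integer(ov)
  }
  t_cpg <- find_tad(pairs$cpg_chrom, pairs$cpg_pos)
  t_snp <- find_tad(pairs$snp_chrom, pairs$snp_pos)
  same_chrom <- as.character(pairs$cpg_chrom) ==
    as.character(pairs$snp_chrom)
  same_tad <- same_chrom & !is.na(t_cpg) & !is.na(t_snp) & t_cpg == t_snp
  sizes <- tibble(type = pairs$type[same_tad],
                  tad_size = GenomicRanges::width(gr)[t_cpg[same_tad]])
  by_type <- tibble(type = pairs$type, same_tad = same_tad,
                    same_chrom = same_chrom) |>
    group_by(.data$type) |>
    summarise(n = n(), n_same_tad = sum(.data$same_tad),
              share = mean(.data$same_tad), .groups = "drop")
  size_test <- NULL
  if (all(c("cis", "trans") %in% sizes$type) &&
      min(table(sizes$type)) >= 2) {
    size_test <- t.test(tad_size ~ type, data = sizes, var.equal = FALSE)
  }
  list(share = mean(same_tad), by_type = by_type,
       n_cross_chrom = sum(!same_chrom), tad_size_test = size_test,
       tad_sizes = sizes)
}
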