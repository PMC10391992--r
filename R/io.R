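#' Read genotypes from VCF or TSV dosage files
#'
#' VCF: the DS (dosage) FORMAT field is preferred; otherwise GT is summed
#' (missing genotypes become `NA`). Multi-allelic records are skipped with a
#' warning. TSV dosage dialect: first column sample ids, remaining columns
#' one SNP each; SNP positions come from a separate 4-column map (see
#' [read_positions()]).
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param positions For the TSV dialect, a tibble `snp_id`, `chrom`, `pos`
#'   (e.g. from [read_positions()]).
#' @param cohort Cohort label assigned to all samples (default "cohort1").
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("auto", "vcf", "tsv"),
                           positions = NULL, cohort = "cohort1") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (dialect == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", v@fix[, "ALT"])
    if (any(multi)) {
      warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
      v <- v[!multi, ]
    }
    fmt <- unique(v@gt[, "FORMAT"])
    has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
    if (has_ds) {
      ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      count_alt <- function(g) {
        ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
               vapply(strsplit(gsub("\\|", "/", g), "/"),
                      function(al) sum(al == "1"), numeric(1)))
      }
      ds <- apply(gt, 2, count_alt)
      dimnames(ds) <- dimnames(gt)
    }
    dos <- t(ds)
    af <- colMeans(dos, na.rm = TRUE) / 2
    snps <- tibble(snp_id = v@fix[, "ID"], chrom = v@fix[, "CHROM"],
                   pos = as.numeric(v@fix[, "POS"]),
                   ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                   maf = pmin(af, 1 - af))
    samples <- tibble(sample_id = rownames(dos), cohort = cohort)
    geno_matrix(dos, snps, samples)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    dos <- as.matrix(df[, -1, drop = FALSE])
    rownames(dos) <- df[[1]]
    if (is.null(positions)) {
      abort("TSV dosage dialect needs a positions map")
    }
    idx <- match(colnames(dos), positions$snp_id)
    if (anyNA(idx)) abort("positions map does not cover all SNPs")
    af <- colMeans(dos, na.rm = TRUE) / 2
    snps <- tibble(snp_id = colnames(dos),
                   chrom = as.character(positions$chrom[idx]),
                   pos = positions$pos[idx], ref = "A", alt = "G",
                   maf = pmin(af, 1 - af))
    geno_matrix(dos, snps, tibble(sample_id = rownames(dos),
                                  cohort = cohort))
  }
}

#' Write genotypes as a VCF with GT and DS fields
#'
#' Hard genotypes are rounded from dosage; the DS field carries the dosage
#' to 6 decimals.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       geno$samples$sample_id), collapse = "\t")), con)
  gt_of <- function(d) {
    ifelse(is.na(d), "./.",
           c("0/0", "0/1", "1/1")[pmin(2, pmax(0, round(d))) + 1])
  }
  for (j in seq_len(ncol(geno$dosages))) {
    d <- geno$dosages[, j]
    cells <- paste0(gt_of(d), ":",
                    ifelse(is.na(d), ".", formatC(d, digits = 6,
                                                  format = "f")))
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j],
                       geno$snps$snp_id[j], geno$snps$ref[j],
                       geno$snps$alt[j], ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotype dosages as TSV (rows = samples, cols = SNPs)
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  df <- as.data.frame(geno$dosages)
  df <- cbind(sample_id = geno$samples$sample_id, df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a 4-column position map (id, chrom, pos, strand)
#' @param path TSV path with header.
#' @return Tibble.
#' @export
read_positions <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:3] <- c("snp_id", "chrom", "pos")
  df$chrom <- as.character(df$chrom)
  df
}

#' Write a methylation matrix as TSV (rows = samples, cols = CpGs)
#' @param meth A [meth_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_tsv <- function(meth, path) {
  df <- as.data.frame(meth$values)
  df <- cbind(sample_id = meth$samples$sample_id, df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a methylation TSV written by [write_methylation_tsv()]
#' @param path TSV path.
#' @param cpg_positions Tibble `cpg_id`, `chrom`, `pos`.
#' @param samples Optional tibble `sample_id`, `cohort`.
#' @param stage Stage tag of the stored values.
#' @return A [meth_matrix()].
#' @export
read_methylation_tsv <- function(path, cpg_positions, samples = NULL,
                                 stage = "raw") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  idx <- match(colnames(v), cpg_positions$cpg_id)
  if (anyNA(idx)) abort("cpg positions do not cover all columns")
  samples <- samples %||% tibble(sample_id = df[[1]], cohort = "cohort1")
  if (stage == "raw") {
    meth_matrix(v, cpg_positions[idx, ], samples, stage = "raw")
  } else {
    structure(list(values = v, cpgs = as_tibble(cpg_positions[idx, ]),
                   samples = as_tibble(samples), stage = stage),
              class = "meth_matrix")
  }
}
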