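#' @importFrom utils read.delim write.table packageVersion
NULL

ALCOHOL_LEVELS <- c("abstainer", "low", "intermediate", "high")
BMI_LEVELS <- c("normal", "overweight", "obese")
ACTIVITY_LEVELS <- c("inactive", "low", "medium_high")
YESNO <- c("yes", "no")

#' Read a genotype matrix from VCF or TSV
#'
#' VCF 4.2 (GT calls only) is parsed with `vcfR`; multi-allelic sites are
#' skipped with a warning. The counted allele is oriented to be the minor
#' allele within the loaded cohort: when the ALT allele frequency exceeds
#' 0.5 the counts are flipped and the REF allele recorded as minor (ties at
#' 0.5 keep file orientation). The TSV layout has SNPs as rows with columns
#' `snp_id`, `chrom`, `pos`, `minor_allele` followed by one column per
#' sample (values 0/1/2 or NA).
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"`.
#' @return A `genotype_matrix`: `G` (samples x SNPs, minor-allele counts)
#'   and `snps` (snp_id, chrom, pos, minor_allele, maf).
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic site(s) skipped")
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
      vapply(a, function(al) {
        if (any(al == "." | is.na(al))) return(NA_integer_)
        sum(al == "1")
      }, integer(1))
    }
    G <- t(apply(gt, 1, count_alt))          # snps x samples
    colnames(G) <- colnames(gt)
    minor <- fix[, "ALT"]
    for (i in seq_len(nrow(G))) {
      g <- G[i, ]
      f <- mean(g, na.rm = TRUE) / 2
      if (!is.nan(f) && f > 0.5) {
        G[i, ] <- 2L - g
        minor[i] <- fix[i, "REF"]
      }
    }
    snps <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]), minor_allele = minor,
                       stringsAsFactors = FALSE)
    G <- t(G)
  } else {
    d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("snp_id", "chrom", "pos", "minor_allele")
    if (!all(need %in% colnames(d)))
      stop("genotype TSV must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    snps <- d[, need]
    snps$chrom <- as.character(snps$chrom)
    G <- t(as.matrix(d[, setdiff(colnames(d), need), drop = FALSE]))
    colnames(G) <- snps$snp_id
    storage.mode(G) <- "integer"
    bad <- which(!(G %in% c(0L, 1L, 2L, NA_integer_)))
    if (length(bad))
      stop("genotype values must be 0/1/2/NA (offending entry ", bad[1], ")",
           call. = FALSE)
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id", call. = FALSE)
  if (anyDuplicated(rownames(G))) stop("duplicate sample_id", call. = FALSE)
  snps$maf <- apply(G, 2, function(g)
    if (all(is.na(g))) NA_real_ else compute_maf(g))
  structure(list(G = G, snps = snps), class = "genotype_matrix")
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  d <- cbind(genotypes$snps[, c("snp_id", "chrom", "pos", "minor_allele")],
             as.data.frame(t(genotypes$G)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF 4.2 (GT only)
#'
#' The counted (minor) allele is written as ALT with a placeholder REF;
#' counts 0/1/2 become GT `0/0`, `0/1`, `1/1` and missing `./.`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @export
write_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- rownames(genotypes$G)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gtmap <- c("0/0", "0/1", "1/1")
  ref_of <- c(A = "G", C = "T", G = "A", T = "C")
  s <- genotypes$snps
  for (i in seq_len(ncol(genotypes$G))) {
    g <- genotypes$G[, i]
    gt <- ifelse(is.na(g), "./.", gtmap[g + 1L])
    writeLines(paste(c(s$chrom[i], s$pos[i], s$snp_id[i],
                       ref_of[[s$minor_allele[i]]], s$minor_allele[i],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a methylation beta-value matrix
#'
#' TSV with a `sample_id` column and one column per CpG; values must lie in
#' `[0, 1]`.
#'
#' @param path File path.
#' @return Numeric matrix (samples x CpGs) with sample_id rownames.
#' @export
read_methylation <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(d))
    stop("methylation TSV needs a sample_id column", call. = FALSE)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id", call. = FALSE)
  m <- as.matrix(d[, setdiff(colnames(d), "sample_id"), drop = FALSE])
  rownames(m) <- d$sample_id
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  m
}

#' Write a methylation matrix as TSV
#' @param beta Matrix (samples x CpGs).
#' @param path Output path.
#' @export
write_methylation <- function(beta, path) {
  d <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CpG manifest
#'
#' TSV with columns `chrom`, `pos` (1-based), `cpg_id`, `gene`,
#' `reported_frequency`. Candidate CpGs must have been reported at least
#' twice; rows with `reported_frequency < 2` are rejected.
#'
#' @param path File path.
#' @return Data.frame of CpG records.
#' @export
read_manifest <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "cpg_id", "gene", "reported_frequency")
  if (!all(need %in% colnames(d)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$cpg_id)) stop("duplicate cpg_id", call. = FALSE)
  if (any(d$pos < 1)) stop("positions are 1-based (pos >= 1)", call. = FALSE)
  if (any(d$reported_frequency < 2))
    stop("candidate CpGs require reported_frequency >= 2", call. = FALSE)
  d$chrom <- as.character(d$chrom)
  d[, need[c(3, 1, 2, 4, 5)]]
}

#' Read a cohort covariate/phenotype table
#'
#' Validates category levels (alcohol, BMI class, activity, yes/no
#' variables), the panel label, uniqueness of sample ids, positive
#' follow-up, and the schema rules that cessation time is present only for
#' former smokers and pack-years are zero for never smokers.
#'
#' @param path File path.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id", call. = FALSE)
  chk <- function(col, levels) {
    bad <- !is.na(d[[col]]) & !(d[[col]] %in% levels)
    if (any(bad))
      stop("unknown ", col, " category: ", d[[col]][which(bad)[1]],
           call. = FALSE)
  }
  chk("panel", c("discovery", "validation"))
  chk("smoking_status", c("current", "former", "never"))
  chk("sex", c("male", "female"))
  chk("alcohol", ALCOHOL_LEVELS)
  chk("bmi_class", BMI_LEVELS)
  chk("activity", ACTIVITY_LEVELS)
  for (col in c("cvd", "diabetes", "cancer", "dead")) chk(col, YESNO)
  if (any(!is.na(d$cessation_time) & d$smoking_status != "former"))
    stop("cessation_time present for a non-former smoker", call. = FALSE)
  if (any(d$followup_time <= 0, na.rm = TRUE))
    stop("followup_time must be positive", call. = FALSE)
  if (any(d$pack_years < 0, na.rm = TRUE))
    stop("pack_years must be non-negative", call. = FALSE)
  d
}

#' Write a cohort table as TSV
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a CpG manifest as TSV
#' @param cpgs Manifest data.frame.
#' @param path Output path.
#' @export
write_manifest <- function(cpgs, path) {
  write.table(cpgs[, c("chrom", "pos", "cpg_id", "gene",
                       "reported_frequency")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_result_table <- function(d) {
  for (col in colnames(d)) {
    if (!is.numeric(d[[col]])) next
    if (grepl("(^|_)(p|fdr)$|^p_|_p$|fdr", col, ignore.case = TRUE)) {
      d[[col]] <- ifelse(is.na(d[[col]]), NA,
                         sprintf("%.6e", d[[col]]))
    } else if (!is.integer(d[[col]])) {
      d[[col]] <- ifelse(is.na(d[[col]]), NA,
                         formatC(signif(d[[col]], 6), format = "g",
                                 digits = 6))
    }
  }
  d
}

#' Write result tables and run metadata
#'
#' Each table is written as `<name>.tsv` with its column order preserved;
#' p-value and FDR columns are rendered in scientific notation (six decimal
#' digits of mantissa, so values as small as 1e-308 survive a round trip)
#' and other non-integer numerics to six significant digits. A
#' `run_metadata.json` records the configuration hash, seed, package and R
#' versions.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list stored by hash.
#' @param seed Optional seed to record.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(format_result_table(tables[[nm]]), p, sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
    paths <- c(paths, p)
  }
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                digits = NA), tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  meta <- list(config_hash = cfg_hash, seed = seed,
               package_version = as.character(packageVersion("mqtlsmoke")),
               r_version = R.version.string,
               written = names(tables))
  mp <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
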