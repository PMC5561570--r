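#' Build SNP-CpG candidate pairs within a cis window
#'
#' Emits one pair for every SNP on the same chromosome as a CpG whose
#' position lies within `window` bp of it (bounds inclusive). The signed
#' distance is SNP position minus CpG position, so a positive distance means
#' the SNP lies downstream of the CpG. CpGs with no SNP in their window are
#' returned separately as dropped.
#'
#' @param cpgs Data.frame of CpG records (`cpg_id`, `chrom`, `pos`,
#'   optionally `gene`, `reported_frequency`).
#' @param snps Data.frame of SNP records (`snp_id`, `chrom`, `pos`).
#' @param window Half-width of the cis window in bp (default 50 kb).
#' @return A list: `pairs` (data.frame cpg_id, snp_id, chrom, cpg_pos,
#'   snp_pos, distance) and `dropped_cpgs` (ids with no SNP in window).
#' @export
build_pairs <- function(cpgs, snps, window = 50000) {
  stopifnot(window > 0, all(cpgs$pos >= 1), all(snps$pos >= 1))
  out <- vector("list", nrow(cpgs))
  for (j in seq_len(nrow(cpgs))) {
    hit <- snps$chrom == cpgs$chrom[j] &
      snps$pos >= cpgs$pos[j] - window &
      snps$pos <= cpgs$pos[j] + window
    if (!any(hit)) next
    s <- snps[hit, , drop = FALSE]
    out[[j]] <- data.frame(
      cpg_id = cpgs$cpg_id[j], snp_id = s$snp_id, chrom = cpgs$chrom[j],
      cpg_pos = cpgs$pos[j], snp_pos = s$pos,
      distance = s$pos - cpgs$pos[j],
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- data.frame(cpg_id = character(), snp_id = character(),
                        chrom = character(), cpg_pos = integer(),
                        snp_pos = integer(), distance = integer(),
                        stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  dropped <- setdiff(cpgs$cpg_id, unique(pairs$cpg_id))
  list(pairs = pairs, dropped_cpgs = dropped)
}
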