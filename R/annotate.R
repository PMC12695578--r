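#' Read a gene-region table
#'
#' Regions are 1-based closed intervals (NCBI convention); the file carries
#' an explicit `convention` column to keep the off-by-one contract visible.
#'
#' @param path TSV with columns `gene`, `chrom`, `start`, `end` (and
#'   optionally `convention`); defaults to the packaged PIP2-pathway table.
#'   The packaged table (`pip2_genes_synthetic.tsv`) lists the 27 genes of
#'   the PIP2-hydrolysis pathway with approximate GRCh38 placements
#'   constructed for demonstration and testing; it is synthetic, not an
#'   authoritative annotation.
#' @return Data frame of gene regions.
#' @export
read_gene_table <- function(path = system.file("extdata",
                                               "pip2_genes_synthetic.tsv",
                                               package = "poetriad")) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(chrom = "character"),
                         stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  if (any(g$start > g$end)) stop("gene regions must have start <= end")
  g
}

#' Assign SNPs to gene regions by position
#'
#' A SNP maps to every region whose 1-based closed interval contains its
#' position (same chromosome); SNPs in no region map to none. An optional
#' symmetric flank widens every region.
#'
#' @param snps Data frame with `rsid`, `chrom`, `pos` (e.g. a dataset's
#'   `bim`).
#' @param regions Gene-region data frame from [read_gene_table()].
#' @param flank Basepairs added on both sides of every region (default 0).
#' @return Data frame `rsid`, `gene` with one row per assignment.
#' @export
assign_genes <- function(snps, regions = read_gene_table(), flank = 0) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- snps$chrom == r$chrom &
      snps$pos >= r$start - flank & snps$pos <= r$end + flank
    if (!any(hit)) return(NULL)
    data.frame(rsid = snps$rsid[hit], gene = r$gene,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(rsid = character(0), gene = character(0))
  rownames(out) <- NULL
  out
}

#' Intersect SNP identifiers with an mQTL list
#'
#' Exact-string intersection preserving the order of `snp_ids`; duplicates
#' in either list are removed with a warning.
#'
#' @param snp_ids Character vector of rsIDs (e.g. the POE-significant set).
#' @param mqtl_ids Character vector of methylation-QTL rsIDs.
#' @return The subset of `snp_ids` present in `mqtl_ids`.
#' @export
intersect_mqtl <- function(snp_ids, mqtl_ids) {
  if (anyDuplicated(snp_ids)) {
    warning("duplicate ids in snp_ids removed")
    snp_ids <- unique(snp_ids)
  }
  if (anyDuplicated(mqtl_ids)) {
    warning("duplicate ids in mqtl_ids removed")
    mqtl_ids <- unique(mqtl_ids)
  }
  out <- snp_ids[snp_ids %in% mqtl_ids]
  message(length(out), " of ", length(snp_ids), " SNPs are mQTLs")
  out
}

#' Methylation beta-value from probe intensities
#'
#' beta = max(M, 0) / (max(M, 0) + max(U, 0) + 100), where M and U are the
#' methylated and unmethylated signal intensities; negative intensities are
#' clamped to zero and the +100 offset keeps the denominator positive, so
#' beta always lies in \[0, 1). Vectorized.
#'
#' @param M Methylated signal intensity.
#' @param U Unmethylated signal intensity.
#' @return Methylation fraction estimate in \[0, 1).
#' @export
methylation_beta <- function(M, U) {
  pmax(M, 0) / (pmax(M, 0) + pmax(U, 0) + 100)
}

#' Exploratory two-group comparison of methylation beta-values
#'
#' Utility for contrasting beta at one CpG site between cases and controls
#' (Wilcoxon rank-sum). Exploratory only: the cohort analysis it loosely
#' mirrors does not specify a model, so no reproduction is claimed.
#'
#' @param beta Numeric beta-values.
#' @param group Two-level factor or 0/1 vector.
#' @return List: `delta` (difference of group means, second minus first
#'   level) and `p` (Wilcoxon).
#' @export
beta_group_test <- function(beta, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  sp <- split(beta, group)
  list(delta = mean(sp[[2]], na.rm = TRUE) - mean(sp[[1]], na.rm = TRUE),
       p = stats::wilcox.test(beta ~ group, exact = FALSE)$p.value)
}
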