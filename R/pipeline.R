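# Pipeline orchestration: QC -> per-SNP POE scan -> FDR -> annotation, plus
# the cmd_* entry points behind exec/poetriad. Every cmd_* is a plain
# function so the command line and the library are bit-identical routes.

#' Per-SNP parent-of-origin scan
#'
#' Runs [fit_poe()] at every SNP of a dataset and adjusts the POE p-values
#' by Benjamini-Hochberg across the scanned set.
#'
#' @param dataset A [`genotype_dataset`] (typically post-QC).
#' @param triads A `triad_set`.
#' @param gene_map Optional `rsid`/`gene` data frame from [assign_genes()].
#' @param fdr_subset Optional character vector of rsids: adjust within this
#'   subset only (others get NA); default adjusts over all scanned SNPs.
#' @param ... Passed to [fit_poe()].
#' @return Data frame with one row per SNP: `rsid`, `gene`, `n_triads`,
#'   `ratio`, `ci_low`, `ci_high`, `p_poe`, `p_fdr`, `converged`.
#' @export
poe_scan <- function(dataset, triads, gene_map = NULL, fdr_subset = NULL,
                     ...) {
  rs <- dataset$bim$rsid
  rows <- lapply(rs, function(s) {
    f <- tryCatch(fit_poe(triad_genotypes(dataset, triads, s), ...),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(rsid = s, n_triads = NA_integer_, ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_poe = NA_real_, converged = FALSE))
    data.frame(rsid = s, n_triads = f$n_triads_used, ratio = f$ratio,
               ci_low = f$ratio_ci[1], ci_high = f$ratio_ci[2],
               p_poe = f$p_poe, converged = f$converged)
  })
  out <- do.call(rbind, rows)
  out$gene <- NA_character_
  if (!is.null(gene_map)) {
    agg <- stats::aggregate(gene ~ rsid, gene_map,
                            function(x) paste(unique(x), collapse = ","))
    out$gene <- agg$gene[match(out$rsid, agg$rsid)]
  }
  p_in <- out$p_poe
  if (!is.null(fdr_subset)) p_in[!out$rsid %in% fdr_subset] <- NA
  out$p_fdr <- bh_adjust(p_in)
  out[, c("rsid", "gene", "n_triads", "ratio", "ci_low", "ci_high",
          "p_poe", "p_fdr", "converged")]
}

#' Per-SNP stratified interaction scan
#'
#' Runs [fit_stratified()] at every SNP (or a subset) and adjusts the
#' interaction p-values by Benjamini-Hochberg.
#'
#' @inheritParams poe_scan
#' @param stratum_var Offspring stratification variable (see
#'   [fit_stratified()]).
#' @param snps Optional rsid subset to scan (e.g. the nominally significant
#'   POE set); default all.
#' @return Data frame with one row per (SNP, stratum) plus an `Overall` row:
#'   `rsid`, `stratum`, `ratio`, `ci_low`, `ci_high`, `p_stratum`,
#'   `p_interaction`, `p_interaction_fdr` (interaction columns repeated
#'   across the SNP's rows, as in a long results table).
#' @export
interaction_scan <- function(dataset, triads, stratum_var = "bmi_class",
                             snps = NULL, ...) {
  rs <- if (is.null(snps)) dataset$bim$rsid else snps
  blocks <- lapply(rs, function(s) {
    r <- tryCatch(fit_stratified(dataset, triads, s, stratum_var, ...),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    one <- function(label, f) {
      if (is.null(f)) return(data.frame(
        rsid = s, stratum = label, ratio = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_stratum = NA_real_))
      data.frame(rsid = s, stratum = label, ratio = f$ratio,
                 ci_low = f$ratio_ci[1], ci_high = f$ratio_ci[2],
                 p_stratum = f$p_poe)
    }
    b <- do.call(rbind, c(lapply(names(r$fits),
                                 function(l) one(l, r$fits[[l]])),
                          list(one("Overall", r$overall))))
    b$p_interaction <- r$p_interaction
    b
  })
  out <- do.call(rbind, blocks)
  if (is.null(out)) stop("no SNP could be fitted")
  per_snp <- !duplicated(out$rsid)
  adj <- bh_adjust(out$p_interaction[per_snp])
  out$p_interaction_fdr <- adj[match(out$rsid, out$rsid[per_snp])]
  rownames(out) <- NULL
  out
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.run_log <- function(out_dir, config, seed) {
  lines <- c(paste0("poetriad ", as.character(utils::packageVersion("poetriad"))),
             paste0("R ", R.version.string),
             paste0("seed ", seed %||% "none"),
             paste0("timestamp ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             paste0("config_hash ",
                    sum(utf8ToInt(paste(deparse(config), collapse = "")))))
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}

.load_inputs <- function(plink_prefix, covariates) {
  ds <- read_plink(paste0(plink_prefix, ".bed"))
  cov <- if (!is.null(covariates)) read_covariates(covariates) else NULL
  tri <- assemble_triads(ds, cov)
  list(dataset = ds, triads = tri)
}

#' Pipeline commands
#'
#' Programmatic equivalents of the `poetriad` command-line subcommands.
#' Each writes its outputs under `out_dir` together with a run log
#' (package version, seed, config hash) and returns its main result
#' invisibly. `cmd_fit` runs QC, the per-SNP POE scan and FDR adjustment,
#' writing `poe_results.tsv` (columns mirroring a per-SNP POE results
#' table: ratio, CI bounds, p, FDR-adjusted p). `cmd_interact` adds the
#' stratified fits and writes `interaction_results.tsv`. `cmd_qc` writes
#' the QC report TSVs and the filtered dataset. `cmd_annotate` writes
#' gene assignments and the mQTL intersection. `cmd_simulate` materializes
#' a registered fixture.
#'
#' @param plink_prefix Path prefix of the `.bed`/`.bim`/`.fam` fileset.
#' @param covariates Path to the covariate TSV (see [read_covariates()]).
#' @param out_dir Output directory.
#' @param qc_config Optional YAML file of QC thresholds.
#' @param min_triads Minimum informative triads per fit.
#' @param fix_dd,maternal_effects,test Model options, see [fit_poe()].
#' @param stratum_var Stratification variable for `cmd_interact`.
#' @param snps Optional rsid subset for `cmd_interact`.
#' @param gene_table,mqtl_list,results Paths for `cmd_annotate`: gene-region
#'   TSV, one-column rsID TSV, and a `poe_results.tsv` to annotate.
#' @param alpha Nominal significance cut used to pick the mQTL query set.
#' @param name,dir Fixture name and output directory for `cmd_simulate`.
#' @param seed Seed recorded in the run log (and used by `cmd_simulate`'s
#'   registry entries, which carry fixed seeds of their own).
#' @return The main result data frame (or fixture paths), invisibly.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_qc <- function(plink_prefix, covariates, out_dir,
                   qc_config = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- if (is.null(qc_config)) qc_thresholds() else read_qc_config(qc_config)
  inp <- .load_inputs(plink_prefix, covariates)
  res <- apply_qc(inp$dataset, inp$triads, th)
  write_qc_report(res$report, out_dir)
  write_plink(res$dataset, file.path(out_dir, "filtered"))
  .run_log(out_dir, list(plink_prefix = plink_prefix, thresholds = th), seed)
  invisible(res)
}

#' @rdname pipeline-commands
#' @export
cmd_fit <- function(plink_prefix, covariates, out_dir, qc_config = NULL,
                    min_triads = 10, fix_dd = FALSE,
                    maternal_effects = FALSE, test = "wald",
                    gene_table = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- if (is.null(qc_config)) qc_thresholds() else read_qc_config(qc_config)
  inp <- .load_inputs(plink_prefix, covariates)
  if (nrow(inp$triads) < min_triads)
    stop("only ", nrow(inp$triads), " triads assembled; --min-triads is ",
         min_triads)
  qc <- apply_qc(inp$dataset, inp$triads, th)
  write_qc_report(qc$report, out_dir)
  gm <- if (!is.null(gene_table))
    assign_genes(qc$dataset$bim, read_gene_table(gene_table)) else NULL
  res <- poe_scan(qc$dataset, qc$triads, gene_map = gm,
                  min_informative = min_triads, fix_dd = fix_dd,
                  maternal_effects = maternal_effects, test = test)
  .write_tsv(res, file.path(out_dir, "poe_results.tsv"))
  .run_log(out_dir, list(plink_prefix = plink_prefix, thresholds = th,
                         min_triads = min_triads, fix_dd = fix_dd,
                         maternal_effects = maternal_effects, test = test),
           seed)
  invisible(res)
}

#' @rdname pipeline-commands
#' @export
cmd_interact <- function(plink_prefix, covariates, out_dir,
                         stratum_var = "bmi_class", snps = NULL,
                         qc_config = NULL, min_triads = 10,
                         fix_dd = FALSE, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- if (is.null(qc_config)) qc_thresholds() else read_qc_config(qc_config)
  inp <- .load_inputs(plink_prefix, covariates)
  qc <- apply_qc(inp$dataset, inp$triads, th)
  res <- interaction_scan(qc$dataset, qc$triads, stratum_var = stratum_var,
                          snps = snps, min_informative = min_triads,
                          fix_dd = fix_dd)
  .write_tsv(res, file.path(out_dir, "interaction_results.tsv"))
  .run_log(out_dir, list(plink_prefix = plink_prefix,
                         stratum_var = stratum_var, min_triads = min_triads),
           seed)
  invisible(res)
}

#' @rdname pipeline-commands
#' @export
cmd_annotate <- function(results, out_dir, plink_prefix = NULL,
                         gene_table = NULL, mqtl_list = NULL, alpha = 0.05,
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- utils::read.table(results, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- list()
  if (!is.null(plink_prefix)) {
    bim <- read_plink(paste0(plink_prefix, ".bed"))$bim
    regions <- if (is.null(gene_table)) read_gene_table()
      else read_gene_table(gene_table)
    gm <- assign_genes(bim[bim$rsid %in% res$rsid, ], regions)
    .write_tsv(gm, file.path(out_dir, "gene_map.tsv"))
    out$gene_map <- gm
  }
  if (!is.null(mqtl_list)) {
    mq <- utils::read.table(mqtl_list, header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    sig <- res$rsid[!is.na(res$p_poe) & res$p_poe < alpha]
    hits <- intersect_mqtl(sig, mq)
    .write_tsv(data.frame(rsid = hits), file.path(out_dir, "mqtl_hits.tsv"))
    out$mqtl_hits <- hits
  }
  .run_log(out_dir, list(results = results, alpha = alpha), seed)
  invisible(out)
}

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(name, dir, seed = NULL) {
  fx <- make_fixture(name, dir)
  invisible(fx[c("prefix", "covariates_path", "truth_path")])
}
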