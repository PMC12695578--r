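#' Quality-control thresholds
#'
#' Container for the per-sample and per-SNP filter thresholds. The defaults
#' are the conventional array-QC values for family data: call rate above 95%
#' at both sample and variant level, exact Hardy-Weinberg P above 1e-6,
#' minor allele frequency above 1%, fewer than 10% Mendelian errors per SNP,
#' fewer than 5% per sample, and per-sample heterozygosity within 3 standard
#' deviations of the founder mean.
#'
#' @param sample_call_rate_min Minimum per-sample call rate.
#' @param snp_call_rate_min Minimum per-SNP call rate.
#' @param hwe_p_min Minimum exact Hardy-Weinberg P (computed on founders).
#' @param maf_min Minimum minor allele frequency.
#' @param snp_mendel_error_max Maximum per-SNP Mendelian error rate.
#' @param sample_mendel_error_max Maximum per-sample Mendelian error rate.
#' @param het_sd_window Allowed heterozygosity deviation in founder SDs.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95,
                          snp_call_rate_min = 0.95,
                          hwe_p_min = 1e-6,
                          maf_min = 0.01,
                          snp_mendel_error_max = 0.10,
                          sample_mendel_error_max = 0.05,
                          het_sd_window = 3) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             snp_call_rate_min = snp_call_rate_min,
             hwe_p_min = hwe_p_min,
             maf_min = maf_min,
             snp_mendel_error_max = snp_mendel_error_max,
             sample_mendel_error_max = sample_mendel_error_max,
             het_sd_window = het_sd_window)
  fr <- unlist(th[names(th) != "het_sd_window"])
  if (any(fr < 0 | fr > 1)) stop("rate thresholds must lie in [0, 1]")
  if (het_sd_window <= 0) stop("het_sd_window must be positive")
  structure(th, class = "qc_thresholds")
}

#' Read QC thresholds from a YAML config
#'
#' Unknown keys are rejected; absent keys take the defaults of
#' [qc_thresholds()].
#'
#' @param path YAML file whose top level (or `qc:` block) holds threshold
#'   names as in [qc_thresholds()].
#' @return A `qc_thresholds` object.
#' @export
read_qc_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$qc)) y <- y$qc
  known <- names(formals(qc_thresholds))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown QC threshold(s): ", paste(bad, collapse = ", "))
  do.call(qc_thresholds, y)
}

#' Per-SNP call rate and minor allele frequency
#'
#' @param dataset A [`genotype_dataset`], or a genotype matrix.
#' @return Data frame with `rsid`, `call_rate`, `maf` (NA when every
#'   genotype at the SNP is missing).
#' @export
snp_summary <- function(dataset) {
  g <- if (inherits(dataset, "genotype_dataset")) dataset$geno else dataset
  n_obs <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_obs)   # allele2 frequency
  maf <- pmin(f, 1 - f)
  maf[n_obs == 0] <- NA_real_
  data.frame(rsid = colnames(g) %||% as.character(seq_len(ncol(g))),
             call_rate = n_obs / nrow(g),
             maf = maf,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of the probabilities of every heterozygote count with
#' the same parity and the same allele totals whose conditional probability
#' does not exceed that of the observed count.
#'
#' @param n_hom1 Count of allele1 homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom2 Count of allele2 homozygotes.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("no data: all genotype counts are zero")
  n_a <- 2 * n_hom1 + n_het            # rarer-or-not allele1 count
  n_b <- 2 * n_hom2 + n_het
  # support: heterozygote counts with the parity of n_a, between
  # max(0, n_a + n_b - 2*min-side constraint) handled by hom nonnegativity
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  # log conditional probability up to a shared constant:
  # P(het) = n! / (n1! het! n2!) * 2^het * n_a! n_b! / (2n)!
  hom1 <- (n_a - hets) / 2
  hom2 <- (n_b - hets) / 2
  logp <- lfactorial(n) - lfactorial(hom1) - lfactorial(hets) -
    lfactorial(hom2) + hets * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Mendelian consistency of one triad genotype triple
#'
#' TRUE iff the child genotype can be produced from one allele of each
#' parent. A triple with any missing member is not countable and returns
#' TRUE. Vectorized over equal-length inputs.
#'
#' @param g_M,g_F,g_C Genotype codes in \{0, 1, 2, NA\} for mother, father,
#'   child.
#' @return Logical vector.
#' @export
mendel_check <- function(g_M, g_F, g_C) {
  ok <- rep(TRUE, length(g_C))
  complete <- !(is.na(g_M) | is.na(g_F) | is.na(g_C))
  m <- g_M[complete]; f <- g_F[complete]; c <- g_C[complete]
  # possible maternal contribution in 0/1 copies of allele2
  m_lo <- ifelse(m == 2, 1L, 0L); m_hi <- ifelse(m == 0, 0L, 1L)
  f_lo <- ifelse(f == 2, 1L, 0L); f_hi <- ifelse(f == 0, 0L, 1L)
  ok[complete] <- c >= m_lo + f_lo & c <= m_hi + f_hi
  ok
}

#' Apply sample- and SNP-level quality control
#'
#' Sample filters run first (call rate, founder-referenced heterozygosity
#' z-score, per-sample Mendelian error rate); failing samples are removed
#' together with every triad containing them. SNP filters are then computed
#' on the surviving samples: call rate, minor allele frequency, exact
#' Hardy-Weinberg P on parents only (founders; offspring are correlated with
#' their parents), and per-SNP Mendelian error rate over the surviving
#' triads. Finally, Mendelian-inconsistent genotypes at surviving SNPs are
#' set to missing for all three triad members.
#'
#' @param dataset A [`genotype_dataset`].
#' @param triads A `triad_set` from [assemble_triads()].
#' @param thresholds A [qc_thresholds()] object.
#' @return List of class `qc_result`: `dataset` (filtered, inconsistencies
#'   masked), `triads` (surviving triads, rows re-indexed), and `report` (a
#'   `qc_report`: data frames `snp` and `sample` with the statistics, pass
#'   flags and failure reasons, plus the thresholds and the order of
#'   application).
#' @export
apply_qc <- function(dataset, triads, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(triads, "triad_set"),
            inherits(thresholds, "qc_thresholds"))
  g <- dataset$geno
  fam <- dataset$fam
  n_snp <- ncol(g)

  founder <- !(fam$individual_id %in% triads$child_id)

  ## ---- sample statistics --------------------------------------------------
  call_rate_s <- rowMeans(!is.na(g))
  het_rate <- rowMeans(g == 1L, na.rm = TRUE)
  mu <- mean(het_rate[founder], na.rm = TRUE)
  sdv <- stats::sd(het_rate[founder], na.rm = TRUE)
  het_z <- if (is.na(sdv) || sdv == 0) rep(0, nrow(g)) else (het_rate - mu) / sdv

  # Mendelian errors: attribute each inconsistent (triad, SNP) to all three
  # members; denominator = countable (all-complete) triad-SNP pairs
  err_cnt <- integer(nrow(g)); tot_cnt <- integer(nrow(g))
  snp_err <- integer(n_snp); snp_tot <- integer(n_snp)
  incons <- matrix(FALSE, nrow(triads), n_snp)
  for (t in seq_len(nrow(triads))) {
    gm <- g[triads$mother_row[t], ]; gf <- g[triads$father_row[t], ]
    gc <- g[triads$child_row[t], ]
    complete <- !(is.na(gm) | is.na(gf) | is.na(gc))
    bad <- complete & !mendel_check(gm, gf, gc)
    incons[t, ] <- bad
    snp_err <- snp_err + bad
    snp_tot <- snp_tot + complete
    for (r in c(triads$mother_row[t], triads$father_row[t], triads$child_row[t])) {
      err_cnt[r] <- err_cnt[r] + sum(bad)
      tot_cnt[r] <- tot_cnt[r] + sum(complete)
    }
  }
  mendel_s <- ifelse(tot_cnt > 0, err_cnt / tot_cnt, 0)

  sample_reason <- character(nrow(g))
  add_reason <- function(reason, flag, current)
    ifelse(flag, ifelse(current == "", reason, paste(current, reason, sep = ";")),
           current)
  sample_reason <- add_reason("call_rate", call_rate_s < thresholds$sample_call_rate_min, sample_reason)
  sample_reason <- add_reason("het", abs(het_z) > thresholds$het_sd_window, sample_reason)
  sample_reason <- add_reason("mendel", mendel_s >= thresholds$sample_mendel_error_max, sample_reason)
  sample_pass <- sample_reason == ""

  sample_report <- data.frame(
    individual_id = fam$individual_id,
    call_rate = call_rate_s, het_rate = het_rate, het_z = het_z,
    mendel_error_rate = mendel_s,
    pass = sample_pass, reasons = sample_reason,
    stringsAsFactors = FALSE)

  ## ---- drop failing samples and their triads ------------------------------
  keep_sample <- sample_pass
  dropped_ids <- fam$individual_id[!keep_sample]
  triad_keep <- !(triads$child_id %in% dropped_ids |
                    triads$mother_id %in% dropped_ids |
                    triads$father_id %in% dropped_ids)
  triads2 <- triads[triad_keep, , drop = FALSE]
  incons <- incons[triad_keep, , drop = FALSE]
  fam2 <- fam[keep_sample, , drop = FALSE]
  g2 <- g[keep_sample, , drop = FALSE]
  if (nrow(fam2) == 0) stop("quality control removed every sample")

  ## ---- SNP statistics on surviving samples --------------------------------
  ss <- snp_summary(g2)
  founder2 <- !(fam2$individual_id %in% triads2$child_id)
  parent_rows <- which(founder2)
  hwe_p <- vapply(seq_len(n_snp), function(j) {
    gj <- g2[parent_rows, j]
    n0 <- sum(gj == 0L, na.rm = TRUE)
    n1 <- sum(gj == 1L, na.rm = TRUE)
    n2 <- sum(gj == 2L, na.rm = TRUE)
    if (n0 + n1 + n2 == 0) return(NA_real_)
    hwe_exact_test(n0, n1, n2)
  }, numeric(1))

  # recompute per-SNP mendel rates over surviving triads only
  snp_err2 <- colSums(incons)
  snp_tot2 <- integer(n_snp)
  for (t in seq_len(nrow(triads2))) {
    gm <- g2[match(triads2$mother_id[t], fam2$individual_id), ]
    gf <- g2[match(triads2$father_id[t], fam2$individual_id), ]
    gc <- g2[match(triads2$child_id[t], fam2$individual_id), ]
    snp_tot2 <- snp_tot2 + !(is.na(gm) | is.na(gf) | is.na(gc))
  }
  mendel_snp <- ifelse(snp_tot2 > 0, snp_err2 / snp_tot2, 0)

  snp_reason <- character(n_snp)
  snp_reason <- add_reason("call_rate", ss$call_rate < thresholds$snp_call_rate_min, snp_reason)
  snp_reason <- add_reason("maf", is.na(ss$maf) | ss$maf < thresholds$maf_min, snp_reason)
  snp_reason <- add_reason("hwe", !is.na(hwe_p) & hwe_p <= thresholds$hwe_p_min, snp_reason)
  snp_reason <- add_reason("mendel", mendel_snp >= thresholds$snp_mendel_error_max, snp_reason)
  snp_pass <- snp_reason == ""

  snp_report <- data.frame(
    rsid = dataset$bim$rsid,
    call_rate = ss$call_rate, maf = ss$maf, hwe_p = hwe_p,
    mendel_error_rate = mendel_snp,
    pass = snp_pass, reasons = snp_reason,
    stringsAsFactors = FALSE)

  ## ---- mask inconsistencies at surviving SNPs -----------------------------
  for (t in seq_len(nrow(triads2))) {
    bad <- incons[t, ] & snp_pass
    if (!any(bad)) next
    rows <- match(c(triads2$mother_id[t], triads2$father_id[t],
                    triads2$child_id[t]), fam2$individual_id)
    g2[rows, bad] <- NA_integer_
  }

  bim2 <- dataset$bim[snp_pass, , drop = FALSE]
  out_ds <- genotype_dataset(fam2, bim2, g2[, snp_pass, drop = FALSE])
  # re-index surviving triads against the filtered sample table
  triads2$child_row <- match(triads2$child_id, fam2$individual_id)
  triads2$mother_row <- match(triads2$mother_id, fam2$individual_id)
  triads2$father_row <- match(triads2$father_id, fam2$individual_id)

  report <- structure(list(snp = snp_report, sample = sample_report,
                           thresholds = thresholds,
                           order = c("sample_filters", "snp_filters",
                                     "mendel_masking")),
                      class = "qc_report")
  structure(list(dataset = out_ds, triads = triads2, report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:",
      sum(!x$sample$pass), "of", nrow(x$sample), "samples removed;",
      sum(!x$snp$pass), "of", nrow(x$snp), "SNPs removed\n")
  if (any(!x$snp$pass)) {
    tab <- table(unlist(strsplit(x$snp$reasons[!x$snp$pass], ";")))
    cat("  SNP failure reasons:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report to TSV files
#'
#' @param report A `qc_report`.
#' @param dir Output directory; writes `snp_qc.tsv` and `sample_qc.tsv`.
#' @return The directory, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$snp, file.path(dir, "snp_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$sample, file.path(dir, "sample_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
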