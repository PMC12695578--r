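# Deterministic packaged fixtures: small on-disk datasets with planted
# structure, regenerated from fixed seeds rather than shipped as files.

.fixture_registry <- c("clean_null", "strong_maternal", "strong_paternal",
                       "bmi_interaction", "qc_violations")

#' Generate a named fixture dataset on disk
#'
#' Writes a deterministic PLINK fileset, covariate TSV and truth-record
#' JSON for one of the registered fixtures:
#' \describe{
#'   \item{clean_null}{200 triads, q = 0.3, all relative risks 1.}
#'   \item{strong_maternal}{500 triads, RRm/RRf = 4 (maternal risk).}
#'   \item{strong_paternal}{500 triads, RRm/RRf = 1/4.}
#'   \item{bmi_interaction}{500 triads per BMI stratum; POE ratio about 36
#'     in the >=28 kg/m^2 stratum against about 2.2 below it.}
#'   \item{qc_violations}{100 triads, 40 SNPs, with planted violations of
#'     each filter: one SNP with 20% Mendelian errors, one near-monomorphic
#'     SNP (MAF about 0.3%), one SNP with every founder heterozygous (gross
#'     HWE violation), one SNP with 10% missingness, one sample with 90%
#'     call rate and one all-heterozygous founder.}
#' }
#'
#' @param name Fixture name from the registry above.
#' @param dir Output directory (created if needed).
#' @return List: `prefix` (PLINK path prefix), `covariates_path`,
#'   `truth_path`, and `expected` (planted items, for qc_violations).
#' @export
make_fixture <- function(name, dir = tempdir()) {
  if (!name %in% .fixture_registry)
    stop("unknown fixture '", name, "'; registry: ",
         paste(.fixture_registry, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, name)
  expected <- NULL

  sim <- switch(
    name,
    clean_null = simulate_triads(sim_config(
      n_triads = 200, q = 0.3, n_snps = 3, seed = 101)),
    strong_maternal = simulate_triads(sim_config(
      n_triads = 500, q = 0.3, rr_m = 2, rr_f = 0.5, n_snps = 3,
      seed = 102)),
    strong_paternal = simulate_triads(sim_config(
      n_triads = 500, q = 0.3, rr_m = 0.5, rr_f = 2, n_snps = 3,
      seed = 103)),
    bmi_interaction = simulate_triads(sim_config(
      n_triads = 500, q = 0.3, n_snps = 3, seed = 104,
      strata = data.frame(label = c("<28", ">=28"), n = c(500, 500),
                          rr_m = c(1.493, 6.033),
                          rr_f = c(1 / 1.493, 1 / 6.033)))),
    qc_violations = simulate_triads(sim_config(
      n_triads = 100, q = 0.3, n_snps = 40, seed = 105))
  )

  if (name == "qc_violations") {
    ds <- sim$dataset
    g <- ds$geno
    tri <- assemble_triads(ds, sim$covariates)
    rs <- ds$bim$rsid

    # SNP 35: 20% of triads get a Mendelian-incompatible child genotype
    bad_tri <- seq(1, 100, by = 5)
    for (t in bad_tri) {
      gm <- g[tri$mother_row[t], 35]; gf <- g[tri$father_row[t], 35]
      for (v in 0:2) if (!mendel_check(gm, gf, v)) {
        g[tri$child_row[t], 35] <- v; break
      }
    }
    # SNP 36: near-monomorphic (4 het carriers among 300 samples)
    g[, 36] <- 0L; g[tri$mother_row[1:4], 36] <- 1L
    # SNP 37: every founder heterozygous (gross HWE violation)
    founder_rows <- c(tri$mother_row, tri$father_row)
    g[founder_rows, 37] <- 1L
    # SNP 38: 10% of samples missing
    g[seq(3, 90, by = 3), 38] <- NA_integer_
    # sample: father of triad 50 missing 4/40 SNPs (call rate 0.9)
    bad_father <- tri$father_id[50]
    g[tri$father_row[50], 1:4] <- NA_integer_
    # sample: mother of triad 60 heterozygous everywhere (het outlier);
    # keep her planted SNPs consistent with the other plants
    het_mother <- tri$mother_id[60]
    g[tri$mother_row[60], ] <- 1L
    g[tri$mother_row[60], 36] <- 0L

    ds <- genotype_dataset(ds$fam, ds$bim, g)
    sim$dataset <- ds
    expected <- list(
      bad_snps = rs[35:38],
      snp_reasons = c("mendel", "maf", "hwe", "call_rate"),
      bad_samples = c(bad_father, het_mother))
  }

  write_plink(sim$dataset, prefix)
  cov_path <- paste0(prefix, "_covariates.tsv")
  utils::write.table(sim$covariates[, c("individual_id", "affected",
                                        "smoking", "drinking", "bmi")],
                     cov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- paste0(prefix, "_truth.json")
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$clean_geno <- NULL   # regenerable; keep the JSON small
  truth$expected <- expected
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  list(prefix = prefix, covariates_path = cov_path,
       truth_path = truth_path, expected = expected, sim = sim)
}
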