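# Quality-control statistics and filters

test_that("snp_summary counts call rate and folded allele frequency", {
  g <- cbind(a = c(0L, 1L, 2L, NA), b = c(0L, 0L, 0L, 0L),
             c = c(2L, 2L, 1L, NA))
  s <- snp_summary(g)
  expect_equal(s$call_rate, c(0.75, 1, 0.75))
  expect_equal(s$maf, c(0.5, 0, 1 / 6))
  g_all_na <- cbind(x = c(NA_integer_, NA_integer_))
  s2 <- snp_summary(g_all_na)
  expect_equal(s2$call_rate, 0)
  expect_true(is.na(s2$maf))
})

test_that("exact HWE test matches hand cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(1, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 2, 0), oracle_hwe(0, 2, 0), tolerance = 1e-12)
  expect_equal(hwe_exact_test(3, 5, 2), oracle_hwe(3, 5, 2), tolerance = 1e-12)
  # a spread of counts, including skewed ones
  for (cnt in list(c(10, 2, 10), c(0, 20, 0), c(25, 10, 1), c(7, 0, 7))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "no data")
  expect_error(hwe_exact_test(-1, 2, 0), "nonnegative")
})

test_that("Mendelian check covers the canonical triples and parent symmetry", {
  expect_false(mendel_check(0, 0, 1))
  expect_true(mendel_check(0, 2, 1))
  expect_false(mendel_check(0, 2, 0))
  expect_true(mendel_check(NA, 0, 2))     # not countable -> consistent
  grid <- expand.grid(m = 0:2, f = 0:2, c = 0:2)
  expect_equal(mendel_check(grid$m, grid$f, grid$c),
               mendel_check(grid$f, grid$m, grid$c))
  # agreement with origin enumeration: consistent iff >= 1 configuration
  n_cfg <- mapply(function(m, f, c) nrow(enumerate_origins(m, f, c)),
                  grid$m, grid$f, grid$c)
  expect_equal(mendel_check(grid$m, grid$f, grid$c), n_cfg > 0)
})

test_that("apply_qc removes exactly the planted violations", {
  fx <- make_fixture("qc_violations", file.path(tempdir(), "qcfix"))
  ds <- read_plink(paste0(fx$prefix, ".bed"))
  tri <- assemble_triads(ds, read_covariates(fx$covariates_path))
  res <- apply_qc(ds, tri)
  rep <- res$report
  expect_setequal(rep$snp$rsid[!rep$snp$pass], fx$expected$bad_snps)
  expect_setequal(rep$sample$individual_id[!rep$sample$pass],
                  fx$expected$bad_samples)
  # each planted SNP fails for its intended reason
  got <- rep$snp$reasons[match(fx$expected$bad_snps, rep$snp$rsid)]
  expect_equal(got, fx$expected$snp_reasons)
  # machine-readable reasons on every filtered item
  expect_true(all(nzchar(rep$snp$reasons[!rep$snp$pass])))
  # pass flags reproducible from stored statistics
  th <- qc_thresholds()
  expect_equal(rep$snp$pass,
               rep$snp$call_rate >= th$snp_call_rate_min &
                 !is.na(rep$snp$maf) & rep$snp$maf >= th$maf_min &
                 (is.na(rep$snp$hwe_p) | rep$snp$hwe_p > th$hwe_p_min) &
                 rep$snp$mendel_error_rate < th$snp_mendel_error_max)
})

test_that("apply_qc is idempotent", {
  fx <- make_fixture("qc_violations", file.path(tempdir(), "qcfix2"))
  ds <- read_plink(paste0(fx$prefix, ".bed"))
  tri <- assemble_triads(ds, read_covariates(fx$covariates_path))
  r1 <- apply_qc(ds, tri)
  r2 <- apply_qc(r1$dataset, r1$triads)
  expect_identical(r2$dataset$geno, r1$dataset$geno)
  expect_equal(nrow(r2$triads), nrow(r1$triads))
  expect_true(all(r2$report$snp$pass))
  expect_true(all(r2$report$sample$pass))
})

test_that("a clean simulated dataset loses nothing to mendel/maf filters", {
  sim <- simulate_triads(n_triads = 200, q = 0.3, n_snps = 8, seed = 31)
  tri <- assemble_triads(sim$dataset, sim$covariates)
  res <- apply_qc(sim$dataset, tri)
  reasons <- unlist(strsplit(res$report$snp$reasons, ";"))
  expect_false(any(reasons %in% c("mendel", "maf")))
  # HWE false positives at P > 1e-6: essentially none expected at 8 SNPs
  expect_false(any(reasons == "hwe"))
})

test_that("QC thresholds validate and round-trip through YAML", {
  expect_error(qc_thresholds(maf_min = 1.2), "\\[0, 1\\]")
  expect_error(qc_thresholds(het_sd_window = 0), "positive")
  path <- file.path(tempdir(), "qc.yaml")
  writeLines(c("qc:", "  maf_min: 0.05", "  hwe_p_min: 1.0e-4"), path)
  th <- read_qc_config(path)
  expect_equal(th$maf_min, 0.05)
  expect_equal(th$hwe_p_min, 1e-4)
  expect_equal(th$snp_call_rate_min, 0.95)   # untouched default
  writeLines(c("qc:", "  nonsense: 1"), path)
  expect_error(read_qc_config(path), "unknown")
})

test_that("QC report writes its two TSVs", {
  fx <- make_fixture("qc_violations", file.path(tempdir(), "qcfix3"))
  ds <- read_plink(paste0(fx$prefix, ".bed"))
  tri <- assemble_triads(ds, read_covariates(fx$covariates_path))
  res <- apply_qc(ds, tri)
  dir <- file.path(tempdir(), "qcrep")
  write_qc_report(res$report, dir)
  snp <- read.table(file.path(dir, "snp_qc.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(snp), 40)
  expect_true(file.exists(file.path(dir, "sample_qc.tsv")))
})
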