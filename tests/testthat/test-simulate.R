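# Ground-truth triad simulator

test_that("same seed gives identical output; different seed differs", {
  a <- simulate_triads(n_triads = 50, q = 0.3, rr_m = 2, seed = 5,
                       missing_rate = 0.05, mendel_error_rate = 0.02)
  b <- simulate_triads(n_triads = 50, q = 0.3, rr_m = 2, seed = 5,
                       missing_rate = 0.05, mendel_error_rate = 0.02)
  c <- simulate_triads(n_triads = 50, q = 0.3, rr_m = 2, seed = 6,
                       missing_rate = 0.05, mendel_error_rate = 0.02)
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$covariates, b$covariates)
  expect_false(identical(a$dataset$geno, c$dataset$geno))
})

test_that("latent transmissions reproduce the pre-corruption children", {
  sim <- simulate_triads(n_triads = 100, q = 0.4, rr_m = 2, n_snps = 4,
                         seed = 13, missing_rate = 0.1,
                         mendel_error_rate = 0.05)
  child_rows <- seq(3, nrow(sim$truth$clean_geno), by = 3)
  expect_identical(sim$truth$clean_geno[child_rows, ],
                   sim$truth$m_trans + sim$truth$f_trans)
  # and parental genotypes can produce the stored transmissions
  gm <- sim$truth$clean_geno[child_rows - 1L, ]
  expect_true(all(sim$truth$m_trans[gm == 0L] == 0L))
  expect_true(all(sim$truth$m_trans[gm == 2L] == 1L))
})

test_that("q = 0 degenerates to all homozygous-allele1 genotypes", {
  sim <- simulate_triads(n_triads = 20, q = 0, seed = 3)
  expect_true(all(sim$dataset$geno == 0L))
})

test_that("under the null, ascertainment leaves the genotype law untouched", {
  sim <- simulate_triads(n_triads = 5000, q = 0.3, seed = 29)
  g <- sim$dataset$geno[, 1]
  parents <- g[sim$dataset$fam$affection == 1L]
  kids <- g[sim$dataset$fam$affection == 2L]
  hw <- c(0.49, 0.42, 0.09)
  expect_lt(max(abs(table(factor(parents, 0:2)) / length(parents) - hw)),
            0.02)
  # children of Hardy-Weinberg random mating are themselves Hardy-Weinberg
  expect_lt(max(abs(table(factor(kids, 0:2)) / length(kids) - hw)), 0.02)
})

test_that("a maternal effect skews the retained transmissions maternally", {
  sim <- simulate_triads(n_triads = 5000, q = 0.3, rr_m = 2, rr_f = 1,
                         seed = 37)
  m <- sum(sim$truth$m_trans); f <- sum(sim$truth$f_trans)
  expect_gt(m, f)
  expect_lt(binom.test(m, m + f, 0.5, "greater")$p.value, 1e-6)
})

test_that("corruption rates land near their nominal values", {
  sim <- simulate_triads(n_triads = 500, q = 0.3, n_snps = 10, seed = 43,
                         missing_rate = 0.05, mendel_error_rate = 0.04)
  expect_lt(abs(mean(is.na(sim$dataset$geno)) - 0.05), 0.01)
  n_err <- nrow(sim$truth$mendel_errors)
  expect_gt(n_err, 0.5 * 0.04 * 500 * 10)   # some draws are uncorruptible
  expect_lt(n_err, 1.5 * 0.04 * 500 * 10)
  # every injected error is detectable before missingness masks it
  t1 <- sim$truth$mendel_errors[1, ]
  rows <- (t1["triad"] - 1) * 3 + 1:3
  tri <- sim$truth$clean_geno[rows, t1["snp"]]
  expect_true(mendel_check(tri[2], tri[1], tri[3]))  # clean was consistent
})

test_that("invalid configurations are rejected at construction", {
  expect_error(sim_config(baseline_b = 0.5, rr_m = 3), "exceeds 1")
  expect_error(sim_config(missing_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(rr_f = 0), "positive")
})

test_that("fixture registry is deterministic and rejects unknown names", {
  expect_error(make_fixture("nope"), "unknown fixture")
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  a <- make_fixture("clean_null", d1)
  b <- make_fixture("clean_null", d2)
  expect_identical(readBin(paste0(a$prefix, ".bed"), "raw", 1e6),
                   readBin(paste0(b$prefix, ".bed"), "raw", 1e6))
})

test_that("the clean_null fixture carries no parent-of-origin signal", {
  fx <- make_fixture("clean_null", file.path(tempdir(), "fx_null"))
  ds <- read_plink(paste0(fx$prefix, ".bed"))
  tri <- assemble_triads(ds, read_covariates(fx$covariates_path))
  f <- fit_poe(triad_genotypes(ds, tri, 1))
  expect_true(f$ratio_ci[1] < 1 && 1 < f$ratio_ci[2])
})
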