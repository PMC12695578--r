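# Origin enumeration, penetrance, and the marginal triad likelihood

test_that("origin enumeration resolves forced and ambiguous triads", {
  o <- enumerate_origins(1, 0, 1)          # only the het mother carries a2
  expect_equal(nrow(o), 1)
  expect_equal(o$maternal, "a2")
  expect_equal(o$paternal, "a1")
  expect_equal(o$weight, 0.5)

  o <- enumerate_origins(1, 1, 1)          # the one ambiguous biallelic case
  expect_equal(nrow(o), 2)
  expect_equal(sort(paste(o$maternal, o$paternal)), c("a1 a2", "a2 a1"))
  expect_equal(o$weight, c(0.25, 0.25))

  o <- enumerate_origins(2, 2, 2)          # forced transmissions
  expect_equal(nrow(o), 1)
  expect_equal(o$weight, 1)

  expect_equal(nrow(enumerate_origins(0, 0, 1)), 0)  # inconsistent
})

test_that("origin weights are Mendelian transmission products", {
  for (gm in 0:2) for (gf in 0:2) {
    total <- 0
    for (gc in 0:2) {
      o <- enumerate_origins(gm, gf, gc)
      if (nrow(o)) total <- total + sum(o$weight)
    }
    expect_equal(total, 1)                 # weights partition over children
    expect_true(all(unlist(lapply(0:2, function(gc)
      enumerate_origins(gm, gf, gc)$weight)) %in% c(1, 0.5, 0.25)))
  }
})

test_that("penetrance factors follow the multiplicative table", {
  p <- poe_params(q = 0.3, rr_m = 2, rr_f = 3, rr_dd = 0.5)
  expect_equal(penetrance_factor(list(c_m = 0, c_f = 0), 0, p), 1)
  expect_equal(penetrance_factor(list(c_m = 1, c_f = 0), 1, p), 2)
  expect_equal(penetrance_factor(list(c_m = 0, c_f = 1), 1, p), 3)
  expect_equal(penetrance_factor(list(c_m = 1, c_f = 1), 2, p), 3)  # 2*3*0.5
  # maternal-genotype effects multiply by the mother's own genotype term
  pm <- poe_params(q = 0.3, rr_m = 2, mat1 = 1.5, mat2 = 4,
                   maternal_effects = TRUE)
  expect_equal(penetrance_factor(list(c_m = 1, c_f = 0), 1, pm), 3)
  expect_equal(penetrance_factor(list(c_m = 1, c_f = 0), 2, pm), 8)
})

test_that("all-null parameters reduce cell probabilities to the prior", {
  pr <- triad_cell_probs(poe_params(q = 0.37))
  oracle <- oracle_joint_table(0.37, 1, 1)
  for (i in seq_len(nrow(pr))) {
    o <- oracle$p[oracle$g_M == pr$g_M[i] & oracle$g_F == pr$g_F[i] &
                    oracle$g_C == pr$g_C[i]]
    expect_equal(pr$prob[i], sum(o), tolerance = 1e-12)
  }
})

test_that("conditional cell probabilities always sum to one", {
  set.seed(42)
  for (i in 1:25) {
    p <- poe_params(q = runif(1, 0.05, 0.95),
                    rr_m = exp(rnorm(1)), rr_f = exp(rnorm(1)),
                    rr_dd = exp(rnorm(1, sd = 0.5)),
                    mat1 = exp(rnorm(1, sd = 0.5)),
                    mat2 = exp(rnorm(1, sd = 0.5)),
                    maternal_effects = i %% 2 == 0)
    expect_equal(sum(triad_cell_probs(p)$prob), 1, tolerance = 1e-12)
  }
})

test_that("triad_loglik equals the brute-force enumeration oracle", {
  sim <- simulate_triads(n_triads = 20, q = 0.3, rr_m = 2, seed = 17)
  g <- sim_triad_geno(sim)
  expect_equal(triad_loglik(g, poe_params(0.3, 2, 1, 1)),
               oracle_triad_loglik(g, 0.3, 2, 1, 1), tolerance = 1e-10)
  # with a missing member marginalized, and maternal effects on
  g[1, 1] <- NA; g[2, 3] <- NA
  expect_equal(
    triad_loglik(g, poe_params(0.4, 1.5, 0.7, 1.2, mat1 = 1.3, mat2 = 0.6,
                               maternal_effects = TRUE)),
    oracle_triad_loglik(g, 0.4, 1.5, 0.7, 1.2, 1.3, 0.6),
    tolerance = 1e-10)
})

test_that("the baseline risk cancels from the conditional likelihood", {
  sim <- simulate_triads(n_triads = 30, q = 0.25, rr_m = 1.5, seed = 19)
  g <- sim_triad_geno(sim)
  a <- oracle_triad_loglik(g, 0.25, 1.5, 1, B = 1)
  b <- oracle_triad_loglik(g, 0.25, 1.5, 1, B = 0.0137)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(triad_loglik(g, poe_params(0.25, 1.5)), a, tolerance = 1e-10)
})

test_that("triads with two or more missing members are dropped", {
  g <- rbind(c(1, 1, 1), c(NA, NA, 1), c(NA, 1, NA))
  expect_equal(triad_loglik(g, poe_params(0.5)),
               triad_loglik(g[1, , drop = FALSE], poe_params(0.5)))
  expect_error(triad_loglik(g[2:3, , drop = FALSE], poe_params(0.5)),
               "no informative")
})

test_that("allele relabelling leaves the maximized log-likelihood unchanged", {
  sim <- simulate_triads(n_triads = 300, q = 0.3, rr_m = 2, rr_f = 0.8,
                         seed = 23)
  g <- sim_triad_geno(sim)
  f1 <- fit_poe(g)
  f2 <- fit_poe(2L - g)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  # and the POE ratio is preserved up to the label swap direction
  expect_equal(log(f1$ratio), -log(f2$ratio), tolerance = 1e-3)
})
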