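# Environment-stratified fits and the POE x E interaction contrast

fake_fit <- function(log_ratio, se) {
  structure(list(ratio = exp(log_ratio), se_log_ratio = se,
                 ratio_ci = exp(log_ratio + c(-1.96, 1.96) * se),
                 p_poe = NA, converged = TRUE),
            class = "poe_fit")
}

test_that("identical fits give z = 0, p = 1", {
  f <- fake_fit(log(4), 0.3)
  it <- interaction_test(f, f)
  expect_equal(unname(it["z"]), 0)
  expect_equal(unname(it["p_interaction"]), 1)
})

test_that("a 3-SE contrast reproduces the normal tail", {
  # se_A, se_B chosen so the pooled SE makes the difference exactly 3 SEs
  f_a <- fake_fit(log(4), sqrt(log(4)^2 / 9 - 0.01))
  f_b <- fake_fit(0, 0.1)
  it <- interaction_test(f_a, f_b)
  expect_equal(unname(it["z"]), 3, tolerance = 1e-10)
  expect_equal(unname(it["p_interaction"]), 2 * pnorm(-3), tolerance = 1e-10)
})

test_that("the contrast is antisymmetric in its arguments", {
  f_a <- fake_fit(0.9, 0.25)
  f_b <- fake_fit(-0.2, 0.4)
  ab <- interaction_test(f_a, f_b)
  ba <- interaction_test(f_b, f_a)
  expect_equal(unname(ab["z"]), -unname(ba["z"]))
  expect_equal(unname(ab["p_interaction"]), unname(ba["p_interaction"]))
  expect_error(interaction_test(f_a, fake_fit(0, NA)), "finite")
})

test_that("stratified fits recover stratum-specific truths", {
  sim <- simulate_triads(sim_config(
    q = 0.3, n_snps = 1, seed = 61,
    strata = data.frame(label = c("<28", ">=28"), n = c(2000, 2000),
                        rr_m = c(1, 2), rr_f = c(1, 0.5))))
  tri <- assemble_triads(sim$dataset, sim$covariates)
  res <- fit_stratified(sim$dataset, tri, 1, "bmi_class")
  lo <- res$fits[["<28"]]; hi <- res$fits[[">=28"]]
  expect_true(lo$ratio_ci[1] < 1 && 1 < lo$ratio_ci[2])
  expect_true(hi$ratio_ci[1] < 4 && 4 < hi$ratio_ci[2])
  expect_lt(res$p_interaction, 0.05)     # ratio 4 vs 1 at n = 2000/stratum
  expect_equal(res$overall$n_triads_used, 4000)
})

test_that("homogeneous strata agree within CI overlap", {
  sim <- simulate_triads(sim_config(
    q = 0.3, seed = 67,
    strata = data.frame(label = c("<28", ">=28"), n = c(2000, 2000),
                        rr_m = c(2, 2), rr_f = c(1, 1))))
  tri <- assemble_triads(sim$dataset, sim$covariates)
  res <- fit_stratified(sim$dataset, tri, 1, "bmi_class")
  lo <- res$fits[["<28"]]; hi <- res$fits[[">=28"]]
  expect_true(lo$ratio_ci[1] < hi$ratio_ci[2] &&
                hi$ratio_ci[1] < lo$ratio_ci[2])
  expect_gt(res$p_interaction, 0.05)
})

test_that("degenerate stratification yields an overall fit only", {
  sim <- simulate_triads(n_triads = 300, q = 0.3, seed = 71)
  tri <- assemble_triads(sim$dataset, sim$covariates)
  tri$smoking <- 1L                      # everyone in one stratum
  res <- fit_stratified(sim$dataset, tri, 1, "smoking")
  expect_true(is.na(res$p_interaction))
  expect_true(inherits(res$overall, "poe_fit"))
})

test_that("an unfit stratum suppresses the interaction test", {
  sim <- simulate_triads(n_triads = 300, q = 0.3, seed = 73)
  tri <- assemble_triads(sim$dataset, sim$covariates)
  tri$smoking <- c(rep(1L, 297), rep(0L, 3))   # 3 triads: below minimum
  res <- fit_stratified(sim$dataset, tri, 1, "smoking")
  expect_true(is.null(res$fits[["0"]]))
  expect_true(is.na(res$p_interaction))
  expect_error(fit_stratified(sim$dataset,
                              transform(tri, smoking = NA_integer_),
                              1, "smoking"),
               "entirely missing")
})
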