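# Ascertainment-conditional likelihood for case-parent triads.
#
# The likelihood depends on the data only through counts of observed
# genotype patterns: the 15 Mendelian-consistent complete triples plus
# patterns with exactly one missing member (marginalized over the missing
# genotype). Triads are tabulated once into (pattern count, cell mask)
# pairs; each likelihood evaluation is then a 15-vector of cell
# probabilities and one matrix product, which keeps large simulation
# studies cheap.

# Tabulate a triad genotype matrix into sufficient statistics.
# g: matrix/data.frame with columns g_M, g_F, g_C (one SNP).
# Returns list(mask = n_pat x 15 logical matrix, count = n_pat vector,
#              n_used, n_dropped_missing, n_dropped_mendel)
.tabulate_triads <- function(g) {
  g <- as.matrix(g)
  if (ncol(g) != 3) stop("triad genotypes must have 3 columns (g_M, g_F, g_C)")
  n_in <- nrow(g)
  nmiss <- rowSums(is.na(g))
  dropped_missing <- sum(nmiss >= 2)
  g <- g[nmiss <= 1, , drop = FALSE]

  if (nrow(g) == 0)
    return(list(mask = matrix(FALSE, 0, nrow(.triad_cells$cells)),
                count = integer(0), n_used = 0L,
                n_dropped_missing = dropped_missing, n_dropped_mendel = 0L))
  key <- paste(g[, 1], g[, 2], g[, 3])   # NA prints as "NA": a valid key
  tab <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(tab), " "),
                                function(x) suppressWarnings(as.integer(x))))
  cells <- .triad_cells$cells
  mask <- matrix(FALSE, nrow(pats), nrow(cells))
  for (i in seq_len(nrow(pats))) {
    ok <- rep(TRUE, nrow(cells))
    for (j in 1:3) if (!is.na(pats[i, j])) ok <- ok & cells[, j] == pats[i, j]
    mask[i, ] <- ok
  }
  informative <- rowSums(mask) > 0
  dropped_mendel <- sum(tab[!informative])
  list(mask = mask[informative, , drop = FALSE],
       count = as.vector(tab)[informative],
       n_used = sum(tab[informative]),
       n_dropped_missing = dropped_missing,
       n_dropped_mendel = dropped_mendel)
}

#' Log-likelihood of case-parent triads under the parent-of-origin model
#'
#' Sum over triads of the log conditional probability of the observed
#' genotype triple given an affected child. Latent parental origins are
#' marginalized; a triad with exactly one missing member is marginalized
#' over the missing genotype; triads with two or more missing members are
#' dropped; Mendelian-inconsistent triples are dropped (treated as missing).
#'
#' @param triads Matrix or data frame with columns `g_M`, `g_F`, `g_C`
#'   (codes 0/1/2/NA), one row per triad, at a single SNP — e.g. from
#'   [triad_genotypes()].
#' @param params A [poe_params()] object.
#' @return Scalar log-likelihood.
#' @export
triad_loglik <- function(triads, params) {
  tab <- .tabulate_triads(triads)
  if (tab$n_used == 0) stop("no informative triads")
  .loglik_from_tab(tab, params)
}

.loglik_from_tab <- function(tab, params) {
  p <- .cell_prob_vector(params)
  pat_p <- as.vector(tab$mask %*% p)
  sum(tab$count * log(pat_p))
}

# parameter transform: theta = (logit q, log rr_m, log rr_f
#                               [, log rr_dd][, log mat1, log mat2])
.theta_to_params <- function(theta, fix_dd, maternal_effects) {
  k <- 3L
  rr_dd <- 1
  if (!fix_dd) { k <- k + 1L; rr_dd <- exp(theta[4]) }
  mat1 <- mat2 <- 1
  if (maternal_effects) {
    mat1 <- exp(theta[k + 1L]); mat2 <- exp(theta[k + 2L])
  }
  poe_params(q = stats::plogis(theta[1]),
             rr_m = exp(theta[2]), rr_f = exp(theta[3]), rr_dd = rr_dd,
             mat1 = mat1, mat2 = mat2, maternal_effects = maternal_effects)
}

#' Fit the parent-of-origin model to case-parent triads
#'
#' Maximizes the ascertainment-conditional marginal likelihood over
#' (logit q, log rr_m, log rr_f, and optionally log rr_dd, log mat1,
#' log mat2) by quasi-Newton search from three starting points (null,
#' maternal-skewed, paternal-skewed). Latent origins and single missing
#' genotypes are marginalized analytically inside the likelihood. Standard
#' errors come from the observed-information matrix at the optimum; the
#' headline quantity is the ratio rr_m/rr_f with a 95% Wald interval and
#' two-sided p-value on the log scale. A likelihood-ratio p-value for
#' rr_m = rr_f is available via `test = "lrt"`.
#'
#' @param triads Triad genotype matrix as for [triad_loglik()].
#' @param fix_dd Fix the double-dose deviation at 1 instead of estimating
#'   it (stabilizes small samples).
#' @param maternal_effects Also estimate maternal-genotype relative risks.
#' @param test `"wald"` (default) or `"lrt"` for the POE p-value.
#' @param min_informative Minimum number of informative triads (default 10).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @param reltol Relative log-likelihood convergence tolerance (default 1e-8).
#' @return Object of class `poe_fit`: `params` (the MLE as [poe_params()]),
#'   `log_cov` (covariance of the transformed parameters), `ratio`,
#'   `ratio_ci`, `p_poe`, `se_log_ratio`, `loglik`, `converged`,
#'   `n_triads_used`, `n_dropped_missing`, `n_dropped_mendel`.
#' @examples
#' sim <- simulate_triads(n_triads = 500, q = 0.3, rr_m = 2, rr_f = 1, seed = 7)
#' tri <- assemble_triads(sim$dataset, sim$covariates)
#' fit <- fit_poe(triad_genotypes(sim$dataset, tri, 1))
#' fit$ratio
#' @export
fit_poe <- function(triads, fix_dd = FALSE, maternal_effects = FALSE,
                    test = c("wald", "lrt"), min_informative = 10,
                    max_iter = 500, reltol = 1e-8) {
  test <- match.arg(test)
  tab <- .tabulate_triads(triads)
  if (tab$n_used < min_informative)
    stop("only ", tab$n_used, " informative triads; need at least ",
         min_informative)

  npar <- 3L + (!fix_dd) + 2L * maternal_effects
  negll <- function(theta) {
    pr <- try(.theta_to_params(theta, fix_dd, maternal_effects), silent = TRUE)
    if (inherits(pr, "try-error")) return(1e10)
    v <- .loglik_from_tab(tab, pr)
    if (!is.finite(v)) 1e10 else -v
  }

  # crude moment start for q from parental allele counts inside the cells
  qhat <- {
    cells <- .triad_cells$cells
    w <- as.vector(crossprod(tab$mask, tab$count))  # triads per cell (spread)
    a2 <- sum((cells[, 1] + cells[, 2]) * w)
    tot <- 4 * sum(w)
    min(max(a2 / tot, 0.02), 0.98)
  }
  base <- c(stats::qlogis(qhat), 0, 0)
  starts <- list(null = base,
                 maternal = base + c(0, log(2), 0),
                 paternal = base + c(0, 0, log(2)))
  starts <- lapply(starts, function(s) c(s, rep(0, npar - 3L)))

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- stats::optim(s, negll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = reltol))
    if (is.null(best) || o$value < best$value) { best <- o }
  }
  conv <- best$convergence == 0
  if (!conv) warning("fit_poe did not converge within max_iter")

  theta <- best$par
  params <- .theta_to_params(theta, fix_dd, maternal_effects)

  H <- pracma::hessian(negll, theta)
  V <- try(solve(H), silent = TRUE)
  singular <- inherits(V, "try-error") || any(!is.finite(V)) ||
    any(diag(as.matrix(V)) <= 0)
  if (singular) {
    V <- matrix(NA_real_, npar, npar)
    warning("observed information is singular; no confidence interval")
  }

  log_ratio <- theta[2] - theta[3]
  se_lr <- if (singular) NA_real_ else sqrt(V[2, 2] + V[3, 3] - 2 * V[2, 3])
  ratio <- exp(log_ratio)
  ci <- if (is.na(se_lr)) c(NA_real_, NA_real_) else
    exp(log_ratio + c(-1, 1) * stats::qnorm(0.975) * se_lr)

  p_poe <- if (test == "wald") {
    if (is.na(se_lr)) NA_real_ else
      min(1, 2 * stats::pnorm(-abs(log_ratio / se_lr)))
  } else {
    # profile out the common transmitted effect under H0: rr_m = rr_f
    negll0 <- function(th0) {
      th <- c(th0[1], th0[2], th0[2], th0[-(1:2)])
      negll(th)
    }
    o0 <- stats::optim(c(theta[1], mean(theta[2:3]),
                         if (npar > 3) theta[4:npar] else NULL),
                       negll0, method = "BFGS",
                       control = list(maxit = max_iter, reltol = reltol))
    lr <- 2 * (o0$value - best$value)
    min(1, stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE))
  }

  structure(list(params = params, log_cov = V,
                 ratio = ratio, ratio_ci = ci, p_poe = p_poe,
                 se_log_ratio = se_lr,
                 loglik = -best$value, converged = conv,
                 n_triads_used = tab$n_used,
                 n_dropped_missing = tab$n_dropped_missing,
                 n_dropped_mendel = tab$n_dropped_mendel,
                 test = test, fix_dd = fix_dd,
                 maternal_effects = maternal_effects),
            class = "poe_fit")
}

#' @export
print.poe_fit <- function(x, ...) {
  cat("Parent-of-origin fit on", x$n_triads_used, "triads\n")
  cat(sprintf("  RRm/RRf = %.3f (95%% CI %.3f-%.3f), p = %.3g [%s]\n",
              x$ratio, x$ratio_ci[1], x$ratio_ci[2], x$p_poe, x$test))
  cat(sprintf("  q = %.3f, RRm = %.3f, RRf = %.3f, RRdd = %.3f%s\n",
              x$params$q, x$params$rr_m, x$params$rr_f, x$params$rr_dd,
              if (x$fix_dd) " (fixed)" else ""))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Tally which parent contributed the risk allele
#'
#' Among case children, counts determinable transmissions of the risk
#' allele: a heterozygous child with a single compatible origin
#' configuration is tallied to the contributing parent; a child homozygous
#' for the risk allele contributes one count to each tally; a fully
#' ambiguous triad (all members heterozygous) is counted separately.
#'
#' @param triads Triad genotype matrix as for [triad_loglik()].
#' @param risk_allele `"a2"` (the counted allele) or `"a1"`.
#' @return Named integer vector `c(n_paternal, n_maternal, n_ambiguous)`.
#' @export
classify_transmission <- function(triads, risk_allele = c("a2", "a1")) {
  risk_allele <- match.arg(risk_allele)
  g <- as.matrix(triads)
  if (risk_allele == "a1") g <- 2L - g          # relabel so risk allele is a2
  n_pat <- 0L; n_mat <- 0L; n_amb <- 0L
  complete <- rowSums(is.na(g)) == 0
  g <- g[complete & mendel_check(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    cfg <- enumerate_origins(g[i, 1], g[i, 2], g[i, 3])
    if (nrow(cfg) == 0) next
    if (nrow(cfg) > 1) { n_amb <- n_amb + 1L; next }
    n_mat <- n_mat + cfg$c_m
    n_pat <- n_pat + cfg$c_f
  }
  c(n_paternal = n_pat, n_maternal = n_mat, n_ambiguous = n_amb)
}
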