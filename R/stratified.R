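#' Fit the parent-of-origin model within environment strata
#'
#' Splits the triads by one offspring covariate (smoking, drinking, BMI
#' class, or offspring sex), fits [fit_poe()] in every stratum and on all
#' triads pooled, and tests whether the log POE ratio differs between
#' strata. Triads with a missing stratum value enter the overall fit only.
#' A stratum below the minimum-triad precondition is reported as unfit and
#' the interaction test is not computed.
#'
#' @param dataset A [`genotype_dataset`].
#' @param triads A `triad_set` from [assemble_triads()].
#' @param snp rsid or column index of the SNP to fit.
#' @param stratum_var One of `"smoking"`, `"drinking"`, `"bmi_class"`,
#'   `"sex"`.
#' @param ... Passed to [fit_poe()].
#' @return Object of class `stratified_result`: `fits` (named list of
#'   per-stratum `poe_fit` or `NULL` when unfit), `overall` (pooled
#'   `poe_fit`), `interaction_z`, `p_interaction` (two strata: Wald
#'   contrast; more: chi-square with strata-1 df and `z` reported as NA),
#'   `stratum_var`, `snp`.
#' @export
fit_stratified <- function(dataset, triads, snp,
                           stratum_var = c("bmi_class", "smoking",
                                           "drinking", "sex"), ...) {
  stratum_var <- match.arg(stratum_var)
  g <- triad_genotypes(dataset, triads, snp)
  v <- triads[[stratum_var]]
  if (all(is.na(v))) stop("stratum variable '", stratum_var,
                          "' is entirely missing")
  v <- if (is.factor(v)) droplevels(factor(v)) else factor(v)
  levs <- levels(v)

  overall <- fit_poe(g, ...)
  fits <- stats::setNames(vector("list", length(levs)), levs)
  for (l in levs) {
    sub <- g[!is.na(v) & v == l, , drop = FALSE]
    fits[l] <- list(tryCatch(fit_poe(sub, ...), error = function(e) NULL))
  }

  z <- NA_real_; p_int <- NA_real_
  ok <- vapply(fits, function(f) !is.null(f) && isTRUE(is.finite(f$se_log_ratio)),
               logical(1))
  if (length(levs) >= 2 && all(ok)) {
    if (length(levs) == 2) {
      it <- interaction_test(fits[[1]], fits[[2]])
      z <- it["z"]; p_int <- it["p_interaction"]
    } else {
      theta <- vapply(fits, function(f) log(f$ratio), numeric(1))
      se2 <- vapply(fits, function(f) f$se_log_ratio^2, numeric(1))
      d <- theta[-1] - theta[1]
      # covariance of contrasts against the reference stratum
      S <- diag(se2[-1], length(d)) + se2[1]
      stat <- drop(t(d) %*% solve(S, d))
      p_int <- min(1, stats::pchisq(stat, df = length(d),
                                    lower.tail = FALSE))
    }
  }
  structure(list(fits = fits, overall = overall,
                 interaction_z = unname(z), p_interaction = unname(p_int),
                 stratum_var = stratum_var, snp = snp),
            class = "stratified_result")
}

#' Wald contrast of the POE ratio between two strata
#'
#' Tests equality of the log POE ratio theta = log(rr_m/rr_f) between two
#' fitted strata: z = (theta_A - theta_B) / sqrt(se_A^2 + se_B^2), with a
#' two-sided normal p-value.
#'
#' @param fit_A,fit_B `poe_fit` objects for the two strata.
#' @return Named numeric vector `c(z, p_interaction)`.
#' @export
interaction_test <- function(fit_A, fit_B) {
  stopifnot(inherits(fit_A, "poe_fit"), inherits(fit_B, "poe_fit"))
  if (!is.finite(fit_A$se_log_ratio) || !is.finite(fit_B$se_log_ratio))
    stop("interaction test requires finite log-ratio standard errors")
  th_a <- log(fit_A$ratio); th_b <- log(fit_B$ratio)
  z <- (th_a - th_b) / sqrt(fit_A$se_log_ratio^2 + fit_B$se_log_ratio^2)
  c(z = z, p_interaction = min(1, 2 * stats::pnorm(-abs(z))))
}

#' @export
print.stratified_result <- function(x, ...) {
  cat("POE stratified by", x$stratum_var, "at", x$snp, "\n")
  for (l in names(x$fits)) {
    f <- x$fits[[l]]
    if (is.null(f)) cat(sprintf("  %-8s unfit (too few triads)\n", l))
    else cat(sprintf("  %-8s RRm/RRf = %.3f (%.3f-%.3f), p = %.3g\n",
                     l, f$ratio, f$ratio_ci[1], f$ratio_ci[2], f$p_poe))
  }
  cat(sprintf("  overall  RRm/RRf = %.3f, p = %.3g\n",
              x$overall$ratio, x$overall$p_poe))
  cat(sprintf("  p_interaction = %.3g\n", x$p_interaction))
  invisible(x)
}
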