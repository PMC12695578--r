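#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate adjustment: on the ascending sort,
#' adj_(i) = min over j >= i of min(1, m * p_(j) / j), mapped back to the
#' input order and capped at 1. Missing p-values are excluded from m and
#' returned as missing. Delegates the arithmetic to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
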