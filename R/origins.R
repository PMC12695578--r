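# Latent parental-origin bookkeeping for a biallelic locus.
#
# Genotype codes count copies of allele2 ("a2"). An origin configuration
# records, for one triad, which allele the child received from each parent
# together with its Mendelian prior weight (1, 1/2 or 1/4: the product of
# the parents' transmission probabilities, heterozygous parents transmitting
# each allele with probability 1/2).

#' Enumerate the parental-origin configurations of a triad
#'
#' Lists every assignment of a maternally and a paternally transmitted
#' allele compatible with the observed genotype triple, with its Mendelian
#' prior weight. The only genuinely ambiguous biallelic case is the fully
#' heterozygous triad (1, 1, 1), which yields two configurations.
#'
#' @param g_M,g_F,g_C Genotype codes in \{0, 1, 2\} for mother, father,
#'   child (single triad; no missing values).
#' @return Data frame with one row per configuration: `c_m`, `c_f` (copies
#'   of allele2 transmitted, 0 or 1), `maternal`, `paternal` (allele labels
#'   `"a1"`/`"a2"`), and `weight`. Zero rows for a Mendelian-inconsistent
#'   triple.
#' @export
enumerate_origins <- function(g_M, g_F, g_C) {
  stopifnot(length(g_M) == 1, !is.na(g_M), !is.na(g_F), !is.na(g_C),
            g_M %in% 0:2, g_F %in% 0:2, g_C %in% 0:2)
  cm <- if (g_M == 1L) 0:1 else g_M / 2L
  wm <- if (g_M == 1L) c(0.5, 0.5) else 1
  cf <- if (g_F == 1L) 0:1 else g_F / 2L
  wf <- if (g_F == 1L) c(0.5, 0.5) else 1
  grid <- expand.grid(i = seq_along(cm), j = seq_along(cf))
  out <- data.frame(c_m = cm[grid$i], c_f = cf[grid$j],
                    weight = wm[grid$i] * wf[grid$j])
  out <- out[out$c_m + out$c_f == g_C, , drop = FALSE]
  out$maternal <- c("a1", "a2")[out$c_m + 1L]
  out$paternal <- c("a1", "a2")[out$c_f + 1L]
  rownames(out) <- NULL
  out[, c("c_m", "c_f", "maternal", "paternal", "weight")]
}

#' Penetrance factor of one origin configuration
#'
#' The disease-risk multiplier of a child, relative to the baseline, under
#' the parent-of-origin model: one maternally transmitted copy of the risk
#' allele multiplies risk by `rr_m`, one paternally transmitted copy by
#' `rr_f`, a homozygous child additionally by the double-dose deviation
#' `rr_dd`, and (when maternal-genotype effects are enabled) the mother's
#' own genotype contributes `mat1` or `mat2`. The baseline itself is not a
#' parameter: it cancels from the ascertainment-conditional likelihood.
#'
#' @param config One row of [enumerate_origins()] output (or any list with
#'   `c_m`, `c_f` as 0/1 allele2 counts).
#' @param g_M Mother's genotype code (used only for maternal-genotype
#'   effects).
#' @param params A [poe_params()] object.
#' @return Positive scalar.
#' @export
penetrance_factor <- function(config, g_M, params) {
  m <- config$c_m
  f <- config$c_f
  out <- params$rr_m^m * params$rr_f^f * params$rr_dd^(m * f)
  if (isTRUE(params$maternal_effects))
    out <- out * c(1, params$mat1, params$mat2)[g_M + 1L]
  out
}

#' Parent-of-origin model parameters
#'
#' @param q Population frequency of allele2 (the counted allele), in (0,1).
#' @param rr_m Relative risk of one maternally transmitted copy of allele2.
#' @param rr_f Relative risk of one paternally transmitted copy.
#' @param rr_dd Double-dose deviation multiplier for allele2 homozygous
#'   children (1 = purely multiplicative).
#' @param mat1,mat2 Maternal-genotype relative risks for mothers carrying 1
#'   or 2 copies of allele2; only used when `maternal_effects` is TRUE.
#' @param maternal_effects Enable the maternal-genotype terms.
#' @return List of class `poe_params`.
#' @export
poe_params <- function(q, rr_m = 1, rr_f = 1, rr_dd = 1,
                       mat1 = 1, mat2 = 1, maternal_effects = FALSE) {
  if (q <= 0 || q >= 1) stop("q must lie strictly in (0, 1)")
  rr <- c(rr_m, rr_f, rr_dd, mat1, mat2)
  if (any(rr <= 0)) stop("relative risks must be positive")
  structure(list(q = q, rr_m = rr_m, rr_f = rr_f, rr_dd = rr_dd,
                 mat1 = mat1, mat2 = mat2,
                 maternal_effects = maternal_effects),
            class = "poe_params")
}

# ---- internal: the 16-row ordered origin table and its 15-cell index ------

.origin_table <- local({
  rows <- NULL
  for (gm in 0:2) for (gf in 0:2) {
    cm <- if (gm == 1L) 0:1 else gm / 2L
    wm <- if (gm == 1L) c(0.5, 0.5) else 1
    cf <- if (gf == 1L) 0:1 else gf / 2L
    wf <- if (gf == 1L) c(0.5, 0.5) else 1
    for (i in seq_along(cm)) for (j in seq_along(cf))
      rows <- rbind(rows, c(gm, gf, cm[i], cf[j], wm[i] * wf[j]))
  }
  colnames(rows) <- c("g_m", "g_f", "c_m", "c_f", "w")
  rows
})

# the 15 Mendelian-consistent ordered (g_M, g_F, g_C) triples
.triad_cells <- local({
  tb <- .origin_table
  key <- paste(tb[, "g_m"], tb[, "g_f"], tb[, "c_m"] + tb[, "c_f"])
  u <- unique(key)
  cells <- do.call(rbind, lapply(strsplit(u, " "), as.integer))
  colnames(cells) <- c("g_M", "g_F", "g_C")
  list(cells = cells, index = match(key, u))
})

#' Conditional triad-cell probabilities
#'
#' Probability of each of the 15 Mendelian-consistent ordered genotype
#' triples (g_M, g_F, g_C), conditional on the child being affected, under
#' Hardy-Weinberg parental genotypes at frequency `q`, Mendelian
#' transmission, and the multiplicative parent-of-origin penetrance. The
#' ascertainment normalizer is the sum of the unnormalized masses over all
#' configurations, so the probabilities sum to one and the baseline risk
#' cancels.
#'
#' @param params A [poe_params()] object.
#' @return Data frame with columns `g_M`, `g_F`, `g_C`, `prob`.
#' @export
triad_cell_probs <- function(params) {
  p <- .cell_prob_vector(params)
  data.frame(.triad_cells$cells, prob = p)
}

# fast path: probability vector over the 15 cells
.cell_prob_vector <- function(params) {
  tb <- .origin_table
  q <- params$q
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  pen <- params$rr_m^tb[, "c_m"] * params$rr_f^tb[, "c_f"] *
    params$rr_dd^(tb[, "c_m"] * tb[, "c_f"])
  if (isTRUE(params$maternal_effects))
    pen <- pen * c(1, params$mat1, params$mat2)[tb[, "g_m"] + 1L]
  w <- hw[tb[, "g_m"] + 1L] * hw[tb[, "g_f"] + 1L] * tb[, "w"] * pen
  p <- as.vector(rowsum(w, .triad_cells$index))
  p / sum(p)
}
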