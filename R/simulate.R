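# Generator of ascertained case-parent triads with known ground truth.
#
# The generative model is exactly the model the likelihood fits: parental
# genotypes Hardy-Weinberg at frequency q, Mendelian transmission, child
# disease probability baseline_b multiplied by the parent-of-origin
# penetrance, and retention of a proposed triad only when the child is
# affected (rejection-sampling ascertainment). Fitting uncorrupted
# simulated data is therefore a correctly specified problem.

#' Simulation configuration
#'
#' @param n_triads Triads to generate (per stratum when `strata` is given).
#' @param q Frequency of allele2, the risk-allele axis; scalar or one value
#'   per SNP.
#' @param baseline_b Baseline disease probability of a child carrying no
#'   risk alleles (default 0.1, a realistic adult type 2 diabetes
#'   prevalence scale). Validated so that `baseline_b` times the largest
#'   attainable penetrance product stays at or below 1.
#' @param rr_m,rr_f,rr_dd,mat1,mat2 Generating relative risks (see
#'   [poe_params()]); applied to the first ("causal") SNP.
#' @param n_snps Number of SNPs; SNPs beyond the first are null and
#'   unlinked.
#' @param missing_rate Per-genotype missingness probability.
#' @param mendel_error_rate Per-triad-per-SNP probability of corrupting one
#'   genotype to a Mendelian-incompatible value.
#' @param strata Optional data frame describing stratum-specific effects:
#'   columns `label`, `n`, `rr_m`, `rr_f` (optionally `rr_dd`, `mat1`,
#'   `mat2`), one row per stratum of the offspring BMI class.
#' @param seed Integer seed; every draw flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_triads = 200, q = 0.3, baseline_b = 0.1,
                       rr_m = 1, rr_f = 1, rr_dd = 1, mat1 = 1, mat2 = 1,
                       n_snps = 1, missing_rate = 0, mendel_error_rate = 0,
                       strata = NULL, seed = 1) {
  rates <- c(missing_rate, mendel_error_rate, baseline_b)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  rr_all <- c(rr_m, rr_f, rr_dd, mat1, mat2,
              if (!is.null(strata)) unlist(strata[intersect(
                names(strata), c("rr_m", "rr_f", "rr_dd", "mat1", "mat2"))]))
  if (any(rr_all <= 0)) stop("relative risks must be positive")
  max_pen <- max(1, rr_m * rr_f * rr_dd * max(1, mat1, mat2))
  if (!is.null(strata))
    max_pen <- max(max_pen, strata$rr_m * strata$rr_f *
                     (strata$rr_dd %||% 1))
  if (baseline_b * max_pen > 1)
    stop("baseline_b times the maximum penetrance exceeds 1 (",
         format(baseline_b * max_pen, digits = 3), "): not a probability")
  structure(list(n_triads = n_triads, q = q, baseline_b = baseline_b,
                 rr_m = rr_m, rr_f = rr_f, rr_dd = rr_dd,
                 mat1 = mat1, mat2 = mat2, n_snps = n_snps,
                 missing_rate = missing_rate,
                 mendel_error_rate = mendel_error_rate,
                 strata = strata, seed = seed),
            class = "sim_config")
}

# vectorized rejection sampler for one stratum at the causal SNP
.sample_causal <- function(n, q, b, rr_m, rr_f, rr_dd, mat1, mat2, rng_ok) {
  got_m <- integer(0); got_f <- integer(0); got_cm <- integer(0)
  got_cf <- integer(0)
  tries <- 0L
  while (length(got_m) < n) {
    tries <- tries + 1L
    if (tries > 200L) stop("ascertainment unreachable: acceptance ",
                           "probability is effectively zero")
    k <- max(2L * n, 1000L)
    gm <- stats::rbinom(k, 2, q)
    gf <- stats::rbinom(k, 2, q)
    cm <- ifelse(gm == 1L, stats::rbinom(k, 1, 0.5), gm / 2L)
    cf <- ifelse(gf == 1L, stats::rbinom(k, 1, 0.5), gf / 2L)
    pen <- rr_m^cm * rr_f^cf * rr_dd^(cm * cf) * c(1, mat1, mat2)[gm + 1L]
    acc <- stats::runif(k) < b * pen
    got_m <- c(got_m, gm[acc]); got_f <- c(got_f, gf[acc])
    got_cm <- c(got_cm, cm[acc]); got_cf <- c(got_cf, cf[acc])
  }
  idx <- seq_len(n)
  list(g_M = got_m[idx], g_F = got_f[idx],
       c_m = got_cm[idx], c_f = got_cf[idx])
}

#' Simulate ascertained case-parent triads
#'
#' Draws triads under the parent-of-origin generative model until
#' `n_triads` affected children accumulate (per stratum when stratified),
#' attaches offspring covariates, then injects missingness and Mendelian
#' errors. Covariates are assigned independently of genotype except for the
#' BMI class when `strata` supplies stratum-specific relative risks. SNPs
#' beyond the first are null and unlinked to disease.
#'
#' @param config A [sim_config()]; alternatively pass the configuration
#'   fields directly through `...`.
#' @param ... Fields forwarded to [sim_config()] when `config` is missing.
#' @return List: `dataset` (a [`genotype_dataset`] containing parents and
#'   affected children of every triad, disjoint families), `covariates`
#'   (data frame as in [read_covariates()]), and `truth` (the generating
#'   config, per-triad latent transmissions `m_trans`/`f_trans` at each SNP
#'   before corruption, the uncorrupted genotype matrices, and the injected
#'   corruption positions).
#' @export
simulate_triads <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  strata <- config$strata
  if (is.null(strata))
    strata <- data.frame(label = "all", n = config$n_triads,
                         rr_m = config$rr_m, rr_f = config$rr_f,
                         rr_dd = config$rr_dd, mat1 = config$mat1,
                         mat2 = config$mat2, stringsAsFactors = FALSE)
  if (is.null(strata$rr_dd)) strata$rr_dd <- config$rr_dd
  if (is.null(strata$mat1)) strata$mat1 <- config$mat1
  if (is.null(strata$mat2)) strata$mat2 <- config$mat2

  q <- rep_len(config$q, config$n_snps)
  n_tot <- sum(strata$n)

  g_M <- g_F <- m_tr <- f_tr <- matrix(0L, n_tot, config$n_snps)
  stratum_label <- character(n_tot)
  row0 <- 0L
  for (s in seq_len(nrow(strata))) {
    ns <- strata$n[s]
    cz <- .sample_causal(ns, q[1], config$baseline_b,
                         strata$rr_m[s], strata$rr_f[s], strata$rr_dd[s],
                         strata$mat1[s], strata$mat2[s])
    rows <- row0 + seq_len(ns)
    g_M[rows, 1] <- cz$g_M; g_F[rows, 1] <- cz$g_F
    m_tr[rows, 1] <- cz$c_m; f_tr[rows, 1] <- cz$c_f
    stratum_label[rows] <- strata$label[s]
    row0 <- row0 + ns
  }
  # null SNPs: plain Hardy-Weinberg + Mendelian draws, no ascertainment pull
  if (config$n_snps > 1) for (j in 2:config$n_snps) {
    g_M[, j] <- stats::rbinom(n_tot, 2, q[j])
    g_F[, j] <- stats::rbinom(n_tot, 2, q[j])
    m_tr[, j] <- ifelse(g_M[, j] == 1L, stats::rbinom(n_tot, 1, 0.5), g_M[, j] / 2L)
    f_tr[, j] <- ifelse(g_F[, j] == 1L, stats::rbinom(n_tot, 1, 0.5), g_F[, j] / 2L)
  }
  g_C <- m_tr + f_tr

  ## covariates: smoking/drinking independent; BMI tied to stratum labels
  ## only when the strata are BMI classes
  smoking <- stats::rbinom(n_tot, 1, 0.3)
  drinking <- stats::rbinom(n_tot, 1, 0.3)
  bmi <- round(stats::rnorm(n_tot, 24.5, 3.5), 1)
  if (all(strata$label %in% c("<28", ">=28"))) {
    lo <- stratum_label == "<28"
    bmi[lo] <- round(pmin(stats::rnorm(sum(lo), 24, 2.2), 27.9), 1)
    bmi[!lo] <- round(pmax(stats::rnorm(sum(!lo), 30.5, 2.2), 28.0), 1)
  }

  ## assemble the dataset (disjoint families FAM0001..)
  fid <- sprintf("FAM%04d", seq_len(n_tot))
  mid <- paste0(fid, "_M"); pid <- paste0(fid, "_F"); cid <- paste0(fid, "_C")
  fam <- data.frame(
    family_id = rep(fid, each = 3),
    individual_id = as.vector(rbind(pid, mid, cid)),
    father_id = as.vector(rbind("0", "0", pid)),
    mother_id = as.vector(rbind("0", "0", mid)),
    sex = as.vector(rbind(1L, 2L, sample(1:2, n_tot, replace = TRUE))),
    affection = as.vector(rbind(1L, 1L, 2L)),
    stringsAsFactors = FALSE)
  rsid <- sprintf("rs%07d", seq_len(config$n_snps))
  bim <- data.frame(rsid = rsid, chrom = "1", cm = 0,
                    pos = 1000L * seq_len(config$n_snps),
                    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)

  geno <- matrix(NA_integer_, 3 * n_tot, config$n_snps)
  geno[seq(1, 3 * n_tot, by = 3), ] <- g_F
  geno[seq(2, 3 * n_tot, by = 3), ] <- g_M
  geno[seq(3, 3 * n_tot, by = 3), ] <- g_C
  clean_geno <- geno

  ## corruption: Mendelian errors first, then missingness
  err_pos <- NULL
  if (config$mendel_error_rate > 0) {
    hit <- which(matrix(stats::runif(n_tot * config$n_snps), n_tot) <
                   config$mendel_error_rate, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      t <- hit[h, 1]; j <- hit[h, 2]
      tri <- c(g_M[t, j], g_F[t, j], g_C[t, j])
      cand <- NULL
      for (member in 1:3) for (v in 0:2) {
        alt <- tri; alt[member] <- v
        if (!mendel_check(alt[1], alt[2], alt[3]))
          cand <- rbind(cand, c(member, v))
      }
      if (is.null(cand)) next   # e.g. het x het: no single flip can break it
      pick <- cand[sample(nrow(cand), 1), ]
      row <- (t - 1L) * 3L + c(2L, 1L, 3L)[pick[1]]  # member 1=M,2=F,3=C
      geno[row, j] <- pick[2]
      err_pos <- rbind(err_pos, c(triad = t, snp = j, member = pick[1],
                                  value = pick[2]))
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)), nrow(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }

  dataset <- genotype_dataset(fam, bim, geno)
  covariates <- data.frame(individual_id = cid, affected = 1L,
                           smoking = smoking, drinking = drinking,
                           bmi = bmi, stringsAsFactors = FALSE)
  covariates$bmi_class <- bmi_class(covariates$bmi)

  truth <- list(config = config, stratum = stratum_label,
                m_trans = m_tr, f_trans = f_tr,
                clean_geno = clean_geno,
                mendel_errors = err_pos)
  list(dataset = dataset, covariates = covariates, truth = truth)
}
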