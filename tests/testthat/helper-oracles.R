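# Independent oracles used across the suite. Each deliberately takes a
# different route from the package code it checks.

# Brute-force triad log-likelihood: enumerate every (g_M, g_F, c_m, c_f)
# combination with explicit probability products and an explicit baseline B
# (which must cancel). Marginalizes a single missing member by summing the
# matching joint configurations.
oracle_joint_table <- function(q, rr_m, rr_f, rr_dd = 1,
                               mat1 = 1, mat2 = 1, B = 1) {
  rows <- expand.grid(g_M = 0:2, g_F = 0:2, c_m = 0:1, c_f = 0:1)
  trans_p <- function(g, c) {           # P(transmit c copies of a2 | g)
    if (g == 0) return(if (c == 0) 1 else 0)
    if (g == 2) return(if (c == 1) 1 else 0)
    0.5
  }
  rows$p <- mapply(function(gm, gf, cm, cf) {
    stats::dbinom(gm, 2, q) * stats::dbinom(gf, 2, q) *
      trans_p(gm, cm) * trans_p(gf, cf) *
      B * rr_m^cm * rr_f^cf * rr_dd^(cm * cf) * c(1, mat1, mat2)[gm + 1]
  }, rows$g_M, rows$g_F, rows$c_m, rows$c_f)
  rows$g_C <- rows$c_m + rows$c_f
  rows$p <- rows$p / sum(rows$p)
  rows
}

oracle_triad_loglik <- function(g, q, rr_m, rr_f, rr_dd = 1,
                                mat1 = 1, mat2 = 1, B = 1) {
  tab <- oracle_joint_table(q, rr_m, rr_f, rr_dd, mat1, mat2, B)
  ll <- 0
  for (i in seq_len(nrow(g))) {
    gm <- g[i, 1]; gf <- g[i, 2]; gc <- g[i, 3]
    nmiss <- sum(is.na(c(gm, gf, gc)))
    if (nmiss >= 2) next
    keep <- rep(TRUE, nrow(tab))
    if (!is.na(gm)) keep <- keep & tab$g_M == gm
    if (!is.na(gf)) keep <- keep & tab$g_F == gf
    if (!is.na(gc)) keep <- keep & tab$g_C == gc
    pr <- sum(tab$p[keep])
    if (pr == 0) next                   # Mendelian-inconsistent: dropped
    ll <- ll + log(pr)
  }
  ll
}

# Iteratively refined dense grid search over (q, rr_m, rr_f) with rr_dd
# fixed at 1, down to step sizes below `resolution`. Pattern counts and
# cell probabilities are computed by its own code path (no package calls).
oracle_grid_fit <- function(g, resolution = 1e-3) {
  g <- g[stats::complete.cases(g), , drop = FALSE]
  key <- paste(g[, 1], g[, 2], g[, 3])
  counts <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
  n_pat <- as.vector(counts)

  ll_of <- function(q, rm, rf) {
    tab <- oracle_joint_table(q, rm, rf)
    pr <- vapply(seq_len(nrow(pats)), function(i)
      sum(tab$p[tab$g_M == pats[i, 1] & tab$g_F == pats[i, 2] &
                  tab$g_C == pats[i, 3]]), numeric(1))
    if (any(pr == 0)) return(-Inf)
    sum(n_pat * log(pr))
  }

  # center and half-widths in (q, log rr_m, log rr_f) space; each round
  # lays an 11-point grid per axis, recenters on the argmax, and shrinks
  # the half-width to twice the step (so the next grid brackets it)
  ctr <- c(0.5, 0, 0)
  half <- c(0.45, log(8), log(8))
  repeat {
    ax <- lapply(1:3, function(d)
      seq(ctr[d] - half[d], ctr[d] + half[d], length.out = 11))
    ax[[1]] <- pmin(pmax(ax[[1]], 1e-4), 1 - 1e-4)
    best <- c(-Inf, ctr)
    for (q in ax[[1]]) for (lm in ax[[2]]) for (lf in ax[[3]]) {
      v <- ll_of(q, exp(lm), exp(lf))
      if (v > best[1]) best <- c(v, q, lm, lf)
    }
    ctr <- best[2:4]
    step <- half / 5
    # raw-scale resolution: q directly; rr via local delta exp(l+s)-exp(l)
    raw_step <- c(step[1], exp(ctr[2]) * (exp(step[2]) - 1),
                  exp(ctr[3]) * (exp(step[3]) - 1))
    if (all(raw_step < resolution))
      return(list(loglik = best[1], q = ctr[1],
                  rr_m = exp(ctr[2]), rr_f = exp(ctr[3])))
    half <- 2 * step
  }
}

# Hardy-Weinberg exact test by full enumeration with the textbook
# recurrence for the conditional probabilities (distinct from the
# closed-form log-factorial route in the package).
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n_hom2 + n_het
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  # unnormalized probs via the ratio recurrence
  # P(h+2)/P(h) = 4 * hom1(h) * hom2(h) / ((h+2)(h+1))
  p <- numeric(length(hets))
  p[1] <- 1
  if (length(hets) > 1) for (i in 1:(length(hets) - 1)) {
    h <- hets[i]
    hom1 <- (n_a - h) / 2
    hom2 <- (n_b - h) / 2
    p[i + 1] <- p[i] * 4 * hom1 * hom2 / ((h + 2) * (h + 1))
  }
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Step-up Benjamini-Hochberg by the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# small helper: triad genotype matrix straight from a simulation
sim_triad_geno <- function(sim, snp = 1) {
  tri <- assemble_triads(sim$dataset, sim$covariates)
  triad_genotypes(sim$dataset, tri, snp)
}
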