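---
title: "Parent-of-origin effects from case-parent triads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin effects from case-parent triads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poetriad)
```

## The scientific problem

A parent-of-origin effect (POE) is present when an allele's effect on
disease risk depends on which parent transmitted it — the population-level
signature of genomic imprinting. Ordinary case-control association cannot
see this: it observes genotypes, not transmissions. The case-parent triad
design — an affected offspring genotyped together with both biological
parents — can, because the parental genotypes constrain (and often
determine) which allele came from which parent, while simultaneously
immunizing the analysis against population stratification: inference is
conditional on the parental mating type.

`poetriad` implements the full desk workflow for this design: PLINK 1
binary input, triad assembly, family-aware quality control, the
ascertainment-conditional likelihood for parent-of-origin-specific relative
risks, environment-stratified fits with an interaction contrast,
Benjamini–Hochberg FDR, and annotation utilities. A simulator generates
triads from exactly the model the likelihood fits, so every statistical
property of the machinery can be verified against known ground truth.

## The model

Consider one biallelic SNP with alleles $a_1, a_2$ and population frequency
$q$ of $a_2$ (the counted allele of the PLINK `.bim` A2 column). For a
child whose maternally and paternally transmitted alleles are $c_m, c_f$
and whose mother's genotype is $g_M$, the disease probability is taken to
be multiplicative in parent-of-origin-specific relative risks:

$$
P(D) \;=\; B \cdot
\mathrm{RR}_m^{[c_m = a_2]} \cdot
\mathrm{RR}_f^{[c_f = a_2]} \cdot
\mathrm{RR}^{*}_{dd}{}^{[c_m = c_f = a_2]} \cdot
\mathrm{mat}_1^{[g_M = a_1 a_2]} \mathrm{mat}_2^{[g_M = a_2 a_2]},
$$

where $B$ is the baseline risk, $\mathrm{RR}_m$ and $\mathrm{RR}_f$ are the
relative risks of one maternally and one paternally transmitted copy,
$\mathrm{RR}^{*}_{dd}$ lets homozygous children deviate from the purely
multiplicative dose model, and the optional $\mathrm{mat}_1, \mathrm{mat}_2$
terms carry an effect of the mother's own genotype. The headline quantity
is the ratio $\mathrm{RR}_m/\mathrm{RR}_f$: above 1, the allele is more
harmful when maternally inherited.

Parents are assumed Hardy–Weinberg at frequency $q$ with random mating, and
transmission is Mendelian. Conditioning on the ascertainment event — the
child is affected — gives, for an observed triple
$(g_M, g_F, g_C)$,

$$
P(g_M, g_F, g_C \mid D) \;=\;
\frac{\sum_{(c_m, c_f)} P_{HWE}(g_M)\, P_{HWE}(g_F)\,
      P(c_m \mid g_M)\, P(c_f \mid g_F)\, \mathrm{pen}(c_m, c_f, g_M)}
     {Z(\theta)},
$$

where the sum runs over the latent origin configurations consistent with
the triple, $\mathrm{pen}$ is the penetrance product above without $B$, and
$Z$ is the same sum over *all* configurations. $B$ appears in numerator and
denominator alike and cancels, so it is not a parameter of the fit (the
simulator, which needs absolute risks, keeps it explicit). The only
genuinely ambiguous biallelic triple is the fully heterozygous triad
$(1,1,1)$, whose two origin configurations are marginalized; a triad with
exactly one missing member is marginalized over the missing genotype, and
triads with two or more missing members are dropped.

### Sufficient statistics and estimation

The conditional probability depends on the data only through counts of the
15 Mendelian-consistent ordered triples (plus the one-missing marginal
patterns), so the package tabulates the triads once and evaluates the
likelihood as a 15-cell probability vector and one matrix product. This is
what makes the replicated simulation studies below affordable.

Estimation maximizes the marginal likelihood directly over
$(\operatorname{logit} q, \log \mathrm{RR}_m, \log \mathrm{RR}_f,
\log \mathrm{RR}^{*}_{dd}[, \log \mathrm{mat}_1, \log \mathrm{mat}_2])$
with BFGS from three starting points (null, maternal-skewed at
$\mathrm{RR}_m = 2$, paternal-skewed at $\mathrm{RR}_f = 2$), keeping the
best optimum. An EM iteration over the latent origins was considered and
rejected as a default: because the latent structure is marginalized
analytically inside a 15-cell multinomial, EM here reduces to an ECM whose
M-step is the same numerical maximization — it adds an iteration layer
without adding robustness. The test suite instead verifies the maximizer
against an exhaustively refined grid search (resolution $10^{-3}$) on a
fixed 200-triad set, and the likelihood itself against a brute-force
enumeration oracle to $10^{-10}$.

Standard errors come from the observed-information matrix (numerical
Hessian at the optimum); the POE ratio gets a 95% Wald interval and
two-sided p-value on the log scale, matching the ratio-with-CI reporting
convention of triad POE studies. A likelihood-ratio test of
$\mathrm{RR}_m = \mathrm{RR}_f$ is available (`test = "lrt"`); Wald is the
default because it is the statistic the interval visualizes. Convergence
uses a relative log-likelihood tolerance of $10^{-8}$ with at most 500
iterations; a singular information matrix (e.g. a monomorphic SNP) is
flagged and returned without an interval rather than failing.

### Parameter defaults and their reasoning

* `rr_dd` is estimated freely by default — the double-dose deviation is
  part of the model — with `fix_dd = TRUE` offered because joint
  estimation is fragile at a few dozen triads.
* Maternal-genotype effects default to off: they are identifiable here,
  but at realistic triad counts their joint estimation with the
  transmission effects is noisy, and the headline ratio does not require
  them. The capability is tested at $n = 4000$.
* `min_informative = 10` triads is a floor below which no fit is
  attempted; a stratum failing it is reported unfit rather than fitted
  badly.

## Stratified fits and the interaction contrast

Environment stratification uses the offspring's own covariates (smoking,
drinking, BMI class at the 28 kg/m² obesity cut, or offspring sex as a
sensitivity stratification). Each stratum is fitted independently; the
POE×E interaction statistic is the Wald contrast on the log ratio,

$$
z = \frac{\hat\theta_A - \hat\theta_B}
         {\sqrt{se_A^2 + se_B^2}},
\qquad \theta = \log(\mathrm{RR}_m/\mathrm{RR}_f),
$$

two-sided normal. This is the minimal statistic consistent with reporting
per-stratum ratios plus one interaction p-value; with more than two strata
it generalizes to a Wald chi-square on the contrasts against a reference
stratum (df = strata − 1). Interaction p-values across SNPs pass through
the same BH adjustment as the main scan.

## Quality control

Defaults follow standard array practice for family data: call rate above
95% at both sample and SNP level, exact Hardy–Weinberg $P > 10^{-6}$,
MAF above 1%, per-SNP Mendelian error rate below 10%, per-sample below 5%,
heterozygosity within 3 SD. Two choices were genuinely open and are made
explicit:

* **HWE on founders only.** Offspring are correlated with their parents;
  including them inflates the exact test. The heterozygosity z-score
  likewise uses the founder mean/SD.
* **Order of application.** Sample filters run first and take their triads
  with them; SNP statistics are then computed on survivors; finally,
  Mendelian-inconsistent genotypes at surviving SNPs are masked to missing
  for all three members (standard practice when the inconsistency cannot be
  attributed). The order is recorded in the report.

Sex-concordance and ancestry-PCA screens require external reference data
and are out of scope.

## The simulator

`simulate_triads()` draws parental genotypes Hardy–Weinberg at $q$,
transmits Mendelian alleles, computes the child's disease probability as
$B$ times the penetrance product, and retains a proposal only if the child
is affected (rejection sampling, bounded, exact). The generating model is
therefore *identical* to the fitted model — by construction, parameter
recovery is a correctly specified problem, which is precisely what makes
it a valid check of the estimator rather than of the model.

Default conditions are chosen to be realistic for the intended setting:
risk-allele frequency 0.3 (a common array SNP), baseline risk $B = 0.1$
(adult type 2 diabetes prevalence scale), offspring smoking and drinking
prevalence 0.3, BMI normal around 24.5 kg/m² (so roughly one in six
offspring are obese at the 28 cut). Missingness and Mendelian-error
injection default to zero and are switched on where QC is exercised.
Mendelian corruption flips one genotype of a triad to an incompatible
value; for the het×het mating no single flip can create an inconsistency,
so such draws are skipped and the truth record stores what was actually
injected.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: linkage disequilibrium between SNPs
(SNPs beyond the first are null and unlinked), population structure and
assortative mating, genotyping-batch artifacts, informative missingness,
and covariates correlated with genotype. Conclusions about the cohort
behaviour of the pipeline rest on the design's own robustness arguments,
not on these simulations.

## Problem sizes used in verification

The replicated studies in the test suite and acceptance script use sizes
chosen to make Monte-Carlo noise small relative to the bands being
checked: 200 replicates of $n = 2000$ triads per recovery scenario
(log-ratio bias bound 0.1; CI coverage pooled over scenarios), 1000
replicates for type-I error at $\alpha = 0.05$, $n = 5000$ for the
transmission-direction property, and full enumeration for the exact-test
oracles (all HWE count triples with total ≤ 50; 1000 random BH vectors).
The grid-search agreement check runs on a fixed 200-triad set at grid
resolution $10^{-3}$.

## Known limitations

* Biallelic SNPs only; the multi-allelic generalization of the likelihood
  is not implemented, and haplotype-level (multi-SNP) POE is out of scope.
* Parental affection status is read but unused: the likelihood conditions
  only on the offspring's disease (pure triad design, no hybrid
  case-parent/case-control weighting).
* Covariate-adjusted penetrances are not modelled; environment enters only
  through stratification.
* X-linked inheritance is not special-cased.
* The packaged PIP2-pathway gene table is a synthetic stand-in with
  approximate coordinates, intended for demonstrating the annotation
  operations — swap in an authoritative table for real use.

## A worked example

```{r example, eval = FALSE}
fx <- make_fixture("bmi_interaction", tempdir())
ds <- read_plink(paste0(fx$prefix, ".bed"))
tri <- assemble_triads(ds, read_covariates(fx$covariates_path))
qc <- apply_qc(ds, tri)
fit_stratified(qc$dataset, qc$triads, "rs0000001", "bmi_class")
```

The fixture plants a POE ratio of about 36 in the obese stratum against
about 2.2 below the cut; the stratified fit recovers both within their
(wide, as expected at 500 triads/stratum) intervals and the interaction
contrast rejects homogeneity.
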