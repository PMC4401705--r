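---
title: "Bayesian whole-genome regression for a binary trait in family cohorts: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probit whole-genome regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

probitWGR assesses how much a dense panel of common SNPs tells us about a
binary disease outcome in a family-based cohort, and how well different
Bayesian whole-genome regression (WGR) priors predict that outcome for
subjects whose relatives were never seen in training. The motivating
setting is a two-generation longitudinal family study of type 2 diabetes:
a few thousand related subjects, a few hundred thousand common markers,
~18% lifetime case prevalence, and strong non-genetic covariates (sex,
cohort of entry, and age at last contact as an exposure-time proxy).
Because such data are access-restricted, the package ships a simulator
that reproduces the relevant structure with known ground truth; every
claim the test suite makes is a claim about recovery of that truth.

## Model

The outcome is modeled on the liability scale through a probit link:

$$P(y_i = 1 \mid \eta_i) = \Phi(\eta_i), \qquad
\eta_i = \mathbf{w}_i'\boldsymbol\alpha + u_i,$$

where $\mathbf{w}_i$ collects the intercept and non-genetic covariates
(plus optionally two ancestry principal components), $\boldsymbol\alpha$
has a flat prior, and $u_i$ is the genetic term. Binary data are handled
by the standard truncated-normal augmentation: a latent liability
$z_i \sim N(\eta_i, 1)$ is sampled truncated to $(0,\infty)$ for cases
and $(-\infty,0]$ for controls, with the threshold fixed at 0 and the
residual variance fixed at 1 for identification. Every conditional in the
Gibbs cycle is then conjugate.

The genetic term is either a regression on centered dosages,
$u_i = \sum_j (x_{ij} - 2q_j)\beta_j$, with one of four effect priors —

* **Bayesian ridge / G-BLUP** — common Gaussian variance
  $\beta_j \sim N(0, \sigma^2_\beta)$;
* **Bayes A** — per-marker variances $\sigma^2_{\beta j}$ with
  scaled-inverse-$\chi^2$ hyper-priors (marginally scaled-$t$ effects);
* **Bayes C$\pi$** — a spike-and-slab mixture
  $\pi\,\mathbb{1}(\beta_j = 0) + (1-\pi)\,N(0,\sigma^2_\beta)$ with a
  Beta prior on the null mass $\pi$;
* **Bayesian LASSO** — the double-exponential prior as a scale mixture of
  normals, $\beta_j \sim N(0, \tau^2_j)$,
  $\tau^2_j \sim \mathrm{Exp}(\lambda^2/2)$,
  $\lambda^2 \sim \mathrm{Gamma}(0.55, 10^{-4})$;

— or a Gaussian genomic value $\mathbf{u} \sim N(0, \mathbf{G}\sigma^2_u)$
with $\mathbf{G}$ the genomic relationship matrix (`gblup-grm`), sampled
in the eigenbasis of $\mathbf{G}$. The two G-BLUP parameterizations are
mathematically equivalent when the markers entering $\mathbf{G}$ are the
centered dosages; the test suite verifies posterior genetic values
correlate above 0.98 between them.

On the mixture convention: we take $\pi$ to be the prior mass *at zero*,
so the proportion of markers with a genetic signal is $1-\pi$, which is
what the reporting layer prints. The Beta prior is parameterized as
(prior probability, prior counts), default (0.5, 10).

The GRM is the VanRaden estimator
$\mathbf{G} = \mathbf{X}_c\mathbf{X}_c' / 2\sum_j q_j(1-q_j)$ with
frequencies re-estimated from the analysis sample. A variant that
additionally divides by $n$ is available (`scaling = "as-printed"`)
because that form circulates in the literature, but it shrinks every
entry toward zero as the sample grows and contradicts the interpretation
of $\sigma^2_u$, so the un-divided estimator is the default.

Genomic heritability on the liability scale is
$h^2 = \sigma^2_u / (\sigma^2_u + 1)$, applied *per posterior sample*
(mean of ratios, not ratio of means), summarized as posterior mean ± SD.

## Hyperparameters

Where scales are not supplied, they are resolved so the prior mean of the
genomic variance equals $R^2_0/(1-R^2_0)$ with $R^2_0 = 0.5$ of the unit
residual liability variance: all inverse-$\chi^2$ priors use df = 5, and
marker-level scales divide the target variance by the empirical
$\sum_j \overline{x_{c,j}^2}$ — the shift-invariant sample estimator of
$2\sum_j q_j(1-q_j)$ (the two coincide for Hardy–Weinberg hard calls).
Using the centered second moment rather than $q(1-q)$ itself makes the
fitted risk scores exactly invariant to adding a constant to any marker's
dosages, a property the suite tests. The Bayes C$\pi$ slab scale is
further divided by the prior inclusion probability. The Bayesian LASSO
rate/shape defaults (0.0001, 0.55) give a diffuse prior on $\lambda^2$.
Bayes A warns below df = 4, where the marginal scaled-$t$ has such heavy
tails that mixing is known to degrade.

MCMC defaults are 40,000 iterations with 15,000 burn-in, the long-chain
convention for WGR analyses; every analysis in this package's scripts and
tests states its own (shorter) chain lengths, chosen per problem size
from trace inspection at development time. Convergence screening is
automated as a Geweke-style z-score (first 10% vs last 50% of the
retained chain, spectral variance estimates) on every scalar trace.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the models were built for:

* **Pedigree** — `n_families` independent families; each family of size
  ≥ 3 is a founder couple (generation 0, the "original cohort") plus
  full-sib offspring (generation 1, the "offspring cohort"). Family sizes
  default to 4–6; the real study's family-size distribution is not
  public, so this is a conventional choice, not an inferred one.
* **Genotypes** — founders draw two independent alleles per marker with
  frequencies uniform on [0.05, 0.5]; offspring inherit one allele per
  parent per marker (gene dropping). Markers are in linkage equilibrium
  among founders, so *family co-inheritance is the only source of LD*.
  This reproduces the key phenomenon — relatives share long genomic
  stretches, so any marker can proxy a causal one within families — but
  not population-level LD blocks, ascertainment, or genotyping error.
  Passing tests therefore demonstrate correct inference under family
  relatedness, not robustness to real-array artifacts.
* **Phenotype** — a liability threshold model. A fraction `pi_nonnull`
  of markers receives Gaussian effects whose common variance is scaled by
  the realized non-null markers' $\sum 2\hat q_j(1-\hat q_j)$ so the
  genetic-value variance equals $\sigma^2_u = h^2/(1-h^2)$; covariate
  effects default to sex −0.26, cohort −0.40, and 0.016 per year of age
  (liability scale), the magnitudes typical of reported analyses of this
  phenotype; the intercept is solved by bisection on $\Phi$ (tolerance
  1e-6) so expected prevalence matches the target 939/5245 ≈ 0.179; the
  threshold sits at 0, matching the samplers' identification.

All stages are deterministic given the seed; sub-seeds are derived per
stage so genotypes do not change when only the phenotype seed moves.

## Evaluation

Cross-validation assigns *entire families* to folds: families are
shuffled with the seed and placed greedily into the smallest fold by
subject count, so no subject is ever predicted by a model trained on a
relative. Held-out risk scores use posterior-mean fixed effects and
posterior-mean marker effects applied to the held-out genotypes centered
at training frequencies; GRM-parameterized models are refit in the
equivalent ridge parameterization for prediction, since genomic values
for unseen subjects would otherwise require retraining. AUC is the
Mann–Whitney pair statistic (ties one half), reported both as mean ± SD
across per-fold AUCs and pooled over all out-of-fold scores — the two can
differ and the across-fold form matches how such tables are usually
printed.

## Numerical choices

* Truncated-normal draws use log-space inverse-CDF sampling
  (`qnorm(..., log.p = TRUE)`), accurate beyond |η| = 10 where naive
  inversion returns infinities.
* The per-marker Gibbs sweeps are compiled (Rcpp) and update the
  residual in place; they consume R's RNG stream, so entire chains are
  bit-reproducible under `set.seed()`. With the null mass at 0 the
  mixture sweep consumes the same stream as the ridge sweep, making the
  degenerate-mixture equality exact.
* The GRM sampler works in the eigenbasis with a pseudo-inverse over
  eigenvalues above `1e-8 * max(eig)`; the scale update counts only the
  retained dimensions.
* Marker columns are centered but *not* standardized; centering is what
  the GRM/ridge equivalence requires, and per-marker scaling is left to
  the priors.
* Fixed-effect draws outside a configurable bound (default 25) raise a
  quasi-separation warning rather than an error.

## Problem sizes used by the tests and scripts

The shipped analyses run at desk scale: cohorts of 150–420 families
(roughly 500–2,100 subjects), 500–5,000 markers, and chains of
700–10,000 iterations depending on what each check needs. These sizes
were chosen so each statistical property is testable with comfortable
Monte-Carlo margins; the model code itself has no size-dependent
branches, and the full-scale configuration (40,000 iterations, hundreds
of thousands of markers) differs only in cost.

## Known limitations

* **The Bayes C$\pi$ null mass is weakly identified at realistic signal
  strengths.** With $h^2 = 0.5$ spread over ~200 of 2,000 markers and
  ~1,000 subjects, the posterior of $1-\pi$ concentrates near 0.5
  regardless of the simulated proportion — for family *and* unrelated
  designs — while the same sampler pins sparse architectures precisely
  when per-marker effects are strong (the suite demonstrates both). This
  mirrors the long-standing observation that mixture proportions in
  Bayesian-alphabet models are barely estimable from weak polygenic
  signal, and explains why "proportion selected" estimates near 50%
  should not be read as architecture estimates. The acceptance suite
  keeps the literal credible-interval-coverage check, and it documents
  this failure rather than hiding it.
* **The weakly-informative prior leaves a floor under null
  heritability.** With the default scale rule (prior mean of
  $\sigma^2_u$ at 1, df = 5), a cohort simulated with $h^2 = 0$ yields a
  posterior mean $h^2$ of about 0.10 even with the fully informative
  continuous liability observed (identity link) — essentially the prior
  residue — and about 0.24 from binary outcomes at 1,000 subjects and
  2,000 markers, where the probit likelihood carries much less
  information about variance components and the over-parameterized
  marker term can absorb binary noise. Growing the sample (2,000
  subjects, 800 markers) moves the binary-data posterior down to about
  0.15. Null-architecture checks in the acceptance suite document this
  behavior; h² estimates from data of this size and type should always
  be read jointly with the prior.
* Mean-dosage imputation stands in for reference-panel imputation; it
  preserves frequencies but not haplotype information.
* No recombination maps, mutation, ascertainment, or longitudinal exam
  structure in the simulator; no logit/cloglog links; no dominance or
  epistatic relationship matrices.
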