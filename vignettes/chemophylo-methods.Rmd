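---
title: "Models and methods behind chemophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemophylo)
```

chemophylo links three kinds of comparative data across a species
radiation — replicate-level chemical peak tables, single-sensillum
electrophysiology, and a phylogeny — to ask how pheromone production and
its olfactory detection evolve. This vignette explains the models, the
parameters that matter, and the design choices made where the design was
genuinely open. The worked numbers shown by `README.md` and the numbered
scripts under `analysis/` are produced by the code at run time; nothing
here reports a result the tests do not themselves compute.

## The trait model: Brownian motion with Pagel's lambda

Species are not independent samples: a trait drifting along the branches
of a phylogeny makes close relatives resemble each other. Under Brownian
motion a trait observed at the tips is multivariate normal with mean
$\mu\mathbf{1}$ and covariance $\sigma^2 C$, where $C_{ij}$ is the
shared root-to-MRCA path length of tips $i$ and $j$ ([`phylo_covariance()`]).
Pagel's lambda interpolates between this fully phylogenetic covariance
and independence by multiplying the off-diagonal of $C$ by
$\lambda \in [0, 1]$ ([`lambda_transform()`]): $\lambda = 1$ keeps the
Brownian structure, $\lambda = 0$ leaves a star phylogeny.

`fit_lambda()` maximizes the likelihood by profiling $\mu$ and
$\sigma^2$ in closed form by GLS at each candidate $\lambda$ (the
$\sigma^2$ MLE uses divisor $n$, matching the profile likelihood), then
searching $\lambda$ with bounded 1-D optimization started from the grid
$\{0, 0.25, 0.5, 0.75, 1\}$ at tolerance $10^{-6}$; both boundaries are
always evaluated and win ties. $\lambda$ is capped at 1 because values
above 1 can destroy positive semi-definiteness on non-ultrametric trees
(empirical trees in substitutions per site are not ultrametric).
Near-singular covariances — exactly coincident tips from zero-length
branches — are handled by a ridge of $10^{-10} \times \mathrm{tr}(C)$
added with a warning.

Whether signal should be estimated on replicate-level or species-mean
values is an open choice; the package defaults to species means (the
replicate level mixes within-species measurement noise into the
evolutionary model), with `level = "replicate"` available in
`standardize_profiles()`.

## Chemical profile standardization and compound calling

`standardize_profiles()` applies the three-step pipeline: peak areas are
divided by the replicate's total (detector units cancel; relative areas
sum to one), log-transformed, and z-scored per feature across species.
Absent features have relative area zero, so the log uses a pseudocount
of half the smallest nonzero relative area in the table — this preserves
ordering and avoids $-\infty$ without dominating the variance. Columns
that end up constant are set to zero rather than NaN.

A compound is *sex-specific* for a species when it is present — area
above the detection floor (default 0, i.e. any called peak) in at least
half of that sex's virgin replicates — in exactly one sex and absent
from **every** replicate of the other sex. The strict-absence rule
mirrors the qualitative definition (present only in one sex, regardless
of quantity); both knobs (`presence_frac`, `floor`) are exposed. Species
with no sex-specific compound are monomorphic. A male-specific compound
is *transferred* when it appears on at least half of the mated-female
replicates of a producing species while absent from virgin females;
female-specific compounds are never assigned a transfer flag.

Profile similarity is summarized with the Pearson correlation $r$
between species' standardized feature vectors. The correlation (not
$r^2$) is reported: the heatmaps this mirrors span negative values,
which only $r$ can represent; $r^2$ is derivable when needed.

## PGLS and the binary production model

`pgls_fit()` regresses a continuous trait on predictors with residual
covariance $\sigma^2 C(\lambda)$ under three branch-transformation
models: `OLS_star` (identity; ordinary least squares), `BM`
($\lambda = 1$) and `lambda_ML` ($\lambda$ estimated jointly).
`select_model_bic()` picks among them with
$\mathrm{BIC} = k \ln n - 2\ell$, where $k$ counts the regression
coefficients, $\sigma^2$, and $\lambda$ when estimated; ties go to fewer
parameters. This candidate set covers the natural nested extremes around
the lambda transform the signal analysis already uses. Coefficient
p-values come from t statistics on $n - p$ residual degrees of freedom
with the unbiased variance (divisor $n - p$), the usual GLS convention;
the ML variance (divisor $n$) feeds the likelihood and BIC.

For binary production, `phyloglm_fit()` implements a phylogenetic
logistic model in the Ives–Garland spirit: the trait evolves as a
two-state Markov process whose stationary probability at tip $i$ is
$\mathrm{logit}^{-1}(x_i'\beta)$ and whose total switching rate is
$\alpha$; the state correlation of two tips then decays as
$e^{-\alpha d_{ij}}$ with patristic distance. Coefficients are estimated
by GEE with that working correlation; $\alpha$ is selected on a fixed
log-spaced grid by a Gaussian quasi-likelihood of standardized
residuals, with independence as the penalized baseline (one
quasi-likelihood unit, the AIC cost of the extra parameter) so that
independent data collapse exactly to ordinary logistic regression.
Significance is assessed by parametric bootstrap *under the fitted
null*: the tested coefficient is removed, the null refitted, traits
re-simulated from the null Markov process (internal branches use the
mean tip probability, terminal branches the tip's own), and the full
model refitted; the two-sided p-value is
$(1 + \#\{|\beta^*| \ge |\hat\beta|\})/(B + 1)$. The default is
$B = 2000$; the calibration tests use $B = 199$, which keeps the suite
inside a sensible runtime while leaving the p-value granularity (1/200)
fine enough to check the 5% level. Which coefficient's significance to
bootstrap, and whether the bootstrap is parametric, were unspecified
choices; the package bootstraps every non-intercept coefficient,
parametrically, because a nonparametric resample of species would break
the phylogenetic dependence being modeled. Perfect separation is flagged
and coefficients are capped at ±15 on the logit scale.

Two-choice behavioral counts are compared against a 50:50 expectation
with the plain Pearson goodness-of-fit chi-square on 1 df, without
continuity correction; counts are expected post-exclusion (trials where
only one rival was courted are the caller's responsibility to drop).

## Rank-sum comparisons

Distributions of lambda estimates between sexes, and clustering
coefficients between sensilla, are compared with the two-sided
Mann-Whitney rank-sum test. Because clustering coefficients are heavily
tied (multiples of $1/(n-1)$), the package enumerates the exact
permutation null of the rank-sum statistic — midranks included —
whenever the number of group assignments is at most 50,000, and falls
back to the normal approximation with tie and continuity corrections
otherwise. The at1-vs-at4 comparison is run unpaired even though both
coefficients are measured on the same species, mirroring the original
analysis; a paired test would typically be more powerful.

## The detection network

`build_network()` draws a directed edge detector → producer (per
sensillum class) when any male-specific compound of the producer
elicits a mean response strictly above 10 spikes/s in the detector —
responses at or below the threshold are excluded, and negative
(inhibitory) responses never create edges. A species detecting its own
compound carries a self-loop. The *olfactory clustering coefficient* of
a species is the number of other species it detects through a sensillum
class divided by all other species in the panel; self-loops count in
neither numerator nor denominator, so the coefficient spans 0 (no
species detected) to 1 (all detected). The denominator deliberately
includes species whose compounds were absent from the stimulus panel
(they are undetected by construction); multi-compound producers count
once. Monomorphic species are nodes that can detect but never be
detected.

## The reference-quality index

For choosing a mapping reference, the index multiplies annotation
completeness, the proportion of properly paired read pairs, and the
probability that a read with the observed mean MAPQ is correctly
placed: $\mathrm{completeness} \times P_{proper} \times
(1 - 10^{-\overline{MAPQ}/10})$. MAPQ is Phred-scaled, so this is the
only dimensionally coherent reading of the index; the uncorrected
expression $(1 - 10^{MAPQ})$, which is negative for any positive MAPQ,
is available behind `literal = TRUE` for auditing. Ties in
`choose_reference()` break by higher completeness, then lexical id, so
ranking is deterministic and order-invariant.

## What the generators emulate — and what they do not

The synthetic study (`sim_config()` defaults) mirrors the empirical
design the pipeline targets: 99 species on a Yule tree; ~250 chemical
features per sex of which 43 (male) and 9 (female) are sex-specific;
six replicates per species-sex ("more than five"); transfer of 70% of
male-specific compounds; supra-threshold responses uniform on 25–125
spikes/s with sub-threshold noise on [0, 10], sitting exactly against
the exclusion boundary; conspecific detection probability 0.73 (36/49
dimorphic species) and heterospecific detection higher through at1
(0.25) than at4 (0.10). Shared-feature log abundances evolve with
lambda 0.8 in males and 0.2 in females — a strong-vs-weak signal
contrast — and sex-specific production spreads by a gain/loss Markov
process (rates 0.2/0.8), giving the patchy across-clade presence
patterns seen in real compound tables. Replicate noise is log-normal
(areas are positive and right-skewed), parameterized by a CV of 0.3.

The generators do **not** emulate chromatographic reality: no
co-eluting peaks, no feature misalignment across species, no
batch/instrument drift, no dose-response structure in spikes/s, and no
missing strata. Passing the recovery tests therefore shows the
estimators are correct under the stated model, not that peak calling or
feature alignment artifacts cannot bias a real analysis — those steps
are upstream of this package by design.

## Problem sizes and numerical choices

The validation suite uses 100-tip trees with 200 traits per lambda
condition for parameter recovery, 20 replicate studies of 50 + 50
features for the between-sex contrast, and 200 datasets with 199
bootstrap replicates for the logistic type-I-error check; these sizes
give the recovery means and rejection rates stable second digits while
keeping a full run of the suite in the minutes range. Likelihood
evaluations use Cholesky factorization throughout; degenerate inputs
(constant traits, single-class binary responses, zero-total replicates,
collinear predictors) are rejected with informative errors rather than
silently imputed, and features whose lambda fit fails are dropped with
a logged count.

## Known limitations

* Lambda estimates on 0–100 tips are noisy individually; inference is
  designed around their distributions (the rank-sum contrast), not
  single-feature values.
* The binary model's switching rate is selected on a grid, so
  `alpha_phylo` is a coarse summary, and at very strong dependence the
  bootstrap p-values run mildly conservative.
* The unpaired at1-vs-at4 test ignores the pairing of sensilla within
  species.
* Feature alignment across species is assumed done upstream; the reader
  only validates identifier consistency.
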