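---
title: "Bayesian genomic prediction of seedling traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian genomic prediction of seedling traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`magicGP` fits and cross-validates genomic-prediction (GP) models for three
kinds of seedling traits measured on inbred multiparent (MAGIC) barley
lines: an ordinal count of seminal roots (SRN), a continuous seminal root
angle (SRA) carried as an adjusted mean with an uncertainty interval, and
whole-plant transpiration rate (TR) evaluated at a target vapor pressure
deficit (VPD) after segmented-regression preprocessing. A synthetic
MAGIC-population generator with known ground truth makes every stage
testable without external data.

# The shared linear predictor

All models place the same structure on line $i$ in replicate $k$:

$$\eta_{ik} = \beta_{k} + L_i + g_i + g_{Ai}$$

* $\beta_k$ — fixed replicate effects, fitted as a full dummy set (for
  single-record traits this collapses to one intercept);
* $L_i \sim N(0, \sigma^2_L)$ — iid line effects, capturing repeatable
  non-genomic line differences;
* $g_i$, with $\mathbf{g} \sim N(0, \mathbf{G}\sigma^2_g)$ — additive
  genomic effects under the VanRaden method-1 relationship matrix
  $\mathbf{G} = \mathbf{W}\mathbf{W}^\top / (2\sum_j p_j(1-p_j))$, where
  $\mathbf{W}$ holds dosages centered by twice the sample allele
  frequencies. Frequencies are estimated from the sample itself, the
  standard default when founder frequencies are unavailable;
* $g_{Ai}$, with $\mathbf{g}_A \sim N(0, (\mathbf{G}\circ\mathbf{G})\,\sigma^2_{gA})$
  — first-order additive-by-additive epistatic effects. The Hadamard
  square of $\mathbf{G}$ is the classical construction for this
  covariance; it is positive semidefinite by the Schur product theorem.
  We note explicitly that "epistatic" is a statistical label here: with
  modest marker density this component largely captures apparent
  (phantom) epistasis rather than biological interaction.

The five canonical predictor sets are exposed as `model_spec(1:5)`:
R+L, R+G, R+G+G×G, R+L+G, R+L+G+G×G.

# Response families

One Gibbs sampler backs four response families, differing only in how the
working response is formed each iteration:

* **Gaussian** (`fit_gaussian`) — the response is used as is.
* **Interval-censored Gaussian** (`fit_censored`) — each record carries an
  interval $(a_i, b_i)$; non-degenerate records have their latent value
  re-drawn each iteration from $N(\eta_i, \sigma^2_e)$ truncated to the
  interval. Adjusted means with $\pm 2$ standard errors are the intended
  input ($a_i = y_i - 2\,\mathrm{SE}_i$, $b_i = y_i + 2\,\mathrm{SE}_i$).
  Whether "SD" in that convention means the standard error of the
  adjusted mean or a replicate-level SD is ambiguous in practice; the
  package takes the SE of the BLUE as default, and the simulator's
  `obs_sd` argument makes the choice explicit.
* **Ordinal threshold probit** (`fit_ordinal_threshold`) — the observed
  category $c$ arises from a latent liability crossing cut-points
  $\gamma_1 < \dots < \gamma_{C-1}$; liabilities are drawn from truncated
  normals and thresholds from their Albert–Chib uniform full
  conditionals. The residual variance is fixed at 1 (probit
  identification). A location constant can trade between $\beta$ and
  $\gamma$ without changing the likelihood, so `anchored_parameters()`
  reports both vectors minus the mean fixed effect; recovery tests
  compare anchored quantities. A Metropolis-based threshold sampler was
  considered and not implemented: with the replicate counts used here the
  uniform conditionals mix adequately.
* **Log-normal counts** (`fit_lognormal_count`) — counts enter as
  $\log(y+1)$ and delegate to the Gaussian path (identical draw for draw
  at the same seed); fitted values are reported back as
  $\exp(\hat\eta)-1$. Poisson/negative-binomial likelihoods are out of
  scope; the log-normal route is the deliberate, cheaper choice for
  replicated small counts.

## Sampler mechanics and numerical choices

Kernel effects are sampled in the eigenbasis of their kernel:
$u = B\delta$ with $B = V\Lambda^{1/2}$ and $\delta \sim N(0, \sigma^2 I)$.
When the design is balanced across lines the full conditional of
$\delta$ is diagonal, giving $O(n)$ updates; unbalanced designs fall back
to a dense Cholesky solve of the (small) $q \times q$ system. Kernel
eigenvalues below $10^{-10}$ are clipped to zero, and a kernel eigenvalue
below $-10^{-8}$ triggers a warning before clipping. Truncated-normal
draws use the inverse-CDF method with probabilities clamped to
$[10^{-12}, 1-10^{-12}]$ so far-tail intervals cannot produce infinities.

Variance components get scaled-inverse-$\chi^2$ full conditionals. Priors
follow the convention of mainstream Bayesian GP software, made explicit:
each component has `prior_df = 5` degrees of freedom and a scale chosen
so the prior mode equals `prior_r2 = 0.5` times the response variance
split equally among the included random terms, with the complement on the
residual. Chain defaults are 30&#8201;000 iterations, 5&#8201;000 burn-in, thinning 5;
chain length is not a sensitive choice for these conjugate samplers, and
an effective-sample-size warning fires below 100 per variance component.
Empty intermediate ordinal categories keep their thresholds (sampled from
the prior-bounded uniform conditional, with a weak-identification
warning) rather than being merged, preserving the category labels.

Degenerate inputs: a constant response collapses the residual variance
toward the prior floor and fits the constant; a single observed ordinal
category is an error ("degenerate ordinal response"); censoring bounds
with $a > b$ are an error, while $a = y = b$ marks an exact observation.

# Trait preparation

`compute_blues()` fits the two-way fixed-effects model
value = line + replicate by least squares with a sum-to-zero replicate
constraint, so the BLUE is the line estimate at the mean replicate level.
This is a deliberately generic stand-in for design-specific mixed models
(trays, positions): it is exact for randomized complete blocks, and the
operation is the single seam to swap if a richer design model is needed.
Inestimable lines are flagged, never silently dropped.

TR curves are regressed on VPD with both a straight line and a
continuous two-segment model
$\mathrm{TR} = \beta_0 + \beta_1\min(v, bp) + \beta_2\max(0, v-bp)$,
the breakpoint found by grid search (default step 0.01 kPa) over the
interior of the measured range. $R^2$ governs selection, but because the
segmented model nests the linear one a minimum gain is required
(`min_gain = 0.01`, small and configurable); $R^2$ is defined as 0 for a
constant response to avoid 0/0. The downstream trait value is the fitted
TR at 2.7 kPa — a VPD above the observed breakpoints (2.3–2.5 kPa) — with
evaluation outside the fitted range allowed under an extrapolation
warning. Whether the value "at 2.7 kPa" should be a fitted or a raw
measurement is ambiguous; the fitted value is the default and
`prepare_tr_values(at_vpd = )` makes the target explicit.

# Cross-validation

`loo_cross_validate()` supports two leave-one-out units, because
replicated traits admit both readings: **observation** mode removes one
record, so the line's remaining replicates keep informing its effects —
this is the less conservative convention and the default for replicated
data; **line** mode removes all of a line's records and predicts the line
purely through its kernel cross-relationships (iid line effects predict
as 0), the only honest option for single-record traits.

For censored traits a third convention exists in the wild: keeping the
held-out record in the training set as an interval with unknown point
value. This leaks the record's location through its bounds and produces
strikingly high predictive abilities even for models with no genomic
information at all. Very high line-level predictive abilities reported
for iid-line-only models in this literature are consistent with that
convention and not with honest line-level LOO, so the package
implements both:
`retain_bounds = TRUE` reproduces the leaky convention, the flag is
echoed in every result object, and the acceptance suite asserts that the
leaky route strictly beats the honest one on simulated data. Honest
line-level accuracy with ~90 training lines is genuinely modest (the
package's own end-to-end run reports both numbers side by side).

Scores: the halved Brier score
$\mathrm{BS} = \tfrac{1}{2n}\sum_i \sum_c (\hat\pi_{ic} - d_{ic})^2 \in [0,1]$
and PCCC (modal-category accuracy, ties broken toward the lower label —
the decision rule is otherwise undefined) for ordinal fits; Pearson
predictive ability for continuous and count fits, with a constant
prediction vector raised as an explicit "undefined correlation" error
rather than a silent 0. Per-fold chains default to 6&#8201;000/1&#8201;000/5 —
shorter than full fits since only posterior means feed the scores.

# Trait correlations

`polyserial_r()` implements the two-step polyserial estimator (thresholds
from inverse-normal cumulative proportions, then 1-D likelihood
maximization for $\rho$, LRT p-value); the two-step variant matches the
conventional default of the standard polyserial software and is simpler
to verify than full joint ML, which is noted as an extension. Pearson
correlations are used between continuous traits, with pairwise-complete
alignment. `gge_scores()` provides the environment-centered SVD behind a
GGE biplot with symmetric singular-value scaling (the scaling convention
is not standardized; symmetric is the neutral choice). Sample SD
($n-1$) is used throughout.

# The synthetic MAGIC generator

`simulate_magic_genotypes()` builds fully inbred lines (dosages 0/2;
8-way MAGIC recombinant inbred lines are homozygous by construction,
with an optional residual-heterozygosity rate defaulting to 0) as
mosaics of a founder panel: per-marker founder allele frequencies are
uniform on `maf_range`, and each line's genome switches founders in
geometric blocks (`segment_length_mean` markers on average). This
creates realistic local linkage disequilibrium and founder-driven
relatedness without a genetic map — sufficient for kernel and recovery
tests, and deliberately not a model of pedigree, drift, or selection.

Default study conditions mirror the target design: 89 lines, 8 founders,
~20k markers, a 7-category ordinal trait labelled 2–8 scored in 12
replicates, and small line/genomic/epistatic variances against a unit
probit residual. Default thresholds were chosen once so the marginal
category distribution is bell-shaped with most mass on category 5.
The TR generator defaults to 90 lines with 28 linear responders and
breakpoints uniform on 2.3–2.5 kPa inside a 0.4–5.4 kPa grid. (The
source design counts 89 lines for GP but 90 for TR phenotyping; the
generator takes `n_lines` as a parameter and does not resolve that
inconsistency.)

What passing recovery tests do show: the samplers estimate what the
generator encodes, under the generator's assumptions (homogeneous noise,
no genotype-by-environment interaction, marker-tagged genetic signal).
What they cannot show: robustness to structured field noise, map-level
LD patterns, or trait architectures outside the simulated family.

# Problem sizes used in the tests

The mixed-model-equations oracle runs at 30 lines with variance
components fixed (tolerance 0.02 against the direct solve); parameter
recovery uses 400–500 lines (300 lines × 4 replicates for the ordinal
family) with 20&#8201;000-iteration chains, recovering variance fractions
within ±0.10–0.12 and anchored thresholds within ±0.15; the
cross-validation ordering experiment uses 60 lines with reduced per-fold
chains. The end-to-end acceptance script simulates the full 89-line,
20k-marker design and runs line-level LOO with 1&#8201;500-iteration fold
chains. These sizes are the package's reference experiments; all are
regenerated from seeds at run time.

# Known limitations

* No multi-trait models, no Poisson/negative-binomial counts, no
  marker-effect priors beyond the GBLUP-equivalent ridge, no REML.
* Ordinal category probabilities for *new* lines use posterior means of
  thresholds and effects (plug-in), not the full posterior predictive.
* The two-way BLUE model ignores design features finer than replicate.
* LOO refits the model per fold; at hundreds of observation-level folds
  with long chains this is the dominant cost, and fold chains are
  intentionally short.
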