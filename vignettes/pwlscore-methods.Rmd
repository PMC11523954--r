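---
title: "Point-wise linear models and simple prediction scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-wise linear models and simple prediction scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwlscore)
```

## The problem

Response to primary androgen deprivation therapy (ADT) in advanced
prostate cancer is heterogeneous, and clinical covariates alone predict it
poorly. The analysis this package implements treats response as a binary
landmark outcome — a patient who progresses to castration resistance
within two years is a non-responder — and asks whether a small SNP panel
added to routine clinical covariates improves prediction, whether the
fitted model can be distilled into an interpretable signed-sum score, and
whether that score stratifies survival.

The package is organized so that every stage is a plain function on
tabular data: outcome labeling, preprocessing, model fitting, importance
ranking, scoring, and survival evaluation, plus a synthetic-cohort
generator so all of it is testable without patient data.

## Outcome definitions

**PSA progression** requires a single measurement to satisfy three clauses
simultaneously: PSA ≥ 2.0 ng/mL; PSA at least 50 % above the running nadir
(the lowest value strictly *before* the current measurement — the
conventional nadir reading of "a rise from the lowest value"); and the
measurement is the third of three consecutive *strictly* increasing values
each at least 7 days apart (ties break the run; "increases" is read
literally). The progression day is the earliest such measurement, which
makes the call monotone under appended follow-up. Radiographic progression
is accepted as an externally supplied date, never computed.

**Landmark labeling** uses 730 days for "2 years" (a fixed-day landmark is
unambiguous where calendar months are not). Patients progressing on or
before the landmark are non-responders; patients followed at least to the
landmark without progression are responders; patients censored earlier are
excluded and counted, so excluded + responders + non-responders always
equals the input size.

**The 7:3 split** is a simple random split with the validation size equal
to `floor(0.3 n)`. Any deterministic rounding of a 7:3 split of 119
patients yields a validation size of 35 or 36; published cohort sizes that
deviate from this (e.g. when exclusions happen after splitting) cannot be
recovered by a rounding rule, and we do not try.

## Preprocessing

Binary features are coded ±1 (the lexicographically larger level — `1`,
`TRUE`, `"present"` — becomes +1). Quantitative features are z-normalized
with the mean and *sample* standard deviation (n − 1) of the discovery
cohort's non-missing values; the transform is frozen and applied unchanged
to validation data, whose column means are therefore generally non-zero.
Missing values become exactly 0 *after* coding, so a missing quantitative
value acts as the discovery mean and a missing binary value as "neither
level". Ordinal covariates (Gleason score, extent-of-disease grade, N/M
category) are treated as quantitative, which is what lets a single median
weight per feature summarize them. SNPs are coded additively — the
minor-allele count is a quantitative variable — so a heterozygote carries
one unit of effect and a minor homozygote two, consistent with the
Hardy–Weinberg effect formula below. Constant features are rejected by
name rather than silently dropped.

## The point-wise linear model

A generator network $g_\theta : \mathbb{R}^d \to \mathbb{R}^{d+1}$ maps
each preprocessed sample $x_j$ to a weight vector and intercept
$(w_j, b_j)$, and the prediction is $\sigma(w_j^\top x_j + b_j)$. The
model is exactly as expressive as an arbitrary smooth classifier, but its
*explanation* is always a local linear model, which is what the importance
procedure consumes.

**Architecture.** Each hidden layer receives the concatenation of the raw
input and *all* previous layers' outputs (dense "mesh" connectivity), with
rectified-linear activations and a linear head. Defaults: 3 hidden layers
of width 64. The dense connectivity gives short gradient paths and acts as
an implicit regularizer at the cohort sizes this method targets; it is the
minimal concrete reading of a mesh-connected deep unified network, since
no reusable pseudocode exists for the original.

**Training.** Full-batch Adam (learning rate 1e-3), at most 500 epochs,
mean binary cross-entropy plus L2 weight decay (default 1e-4) on all
weight matrices. A stratified 20 % internal holdout provides early
stopping with patience 50; the parameters with the best holdout loss are
kept. The head is initialized near zero so the model starts at
$p = 0.5$ for every sample; hidden layers use He initialization. An
optional penalty $\lambda \lVert w(x) \rVert_2^2$ on the *emitted* weights
(default 0, i.e. off) is available to stabilize very small cohorts. All
randomness — initialization, holdout split, CV folds — flows from one
integer seed, and refitting with the same seed, config and data is
bit-identical. The backpropagation is hand-written and verified against
numerical differentiation in the test suite.

**Hyper-parameter selection** uses stratified 5-fold CV on the discovery
cohort; the default grid crosses weight decay {1e-4, 1e-3, 1e-2} with
depth {2, 3}. Fold sizes are as equal as possible (82 samples give
17/17/16/16/16) and the partition depends only on the seed, so the
elastic-net and boosting baselines reuse the identical folds.
Discovery-cohort performance is reported as the mean over the five
held-out folds; validation performance comes from a single refit on the
full discovery cohort. Stratification is our choice (not stated by the
method's description) to avoid fold-level class degeneracy at n ≈ 80.

## Baselines

Elastic-net logistic regression minimizes cross-entropy plus
$\alpha(\rho\lVert\beta\rVert_1 + (1-\rho)/2 \lVert\beta\rVert_2^2)$
(glmnet, with `strength` = $\alpha$ and `mixing` = $\rho$; default grid
$\alpha \in \{0.001, 0.01, 0.1, 1\}$, $\rho \in \{0.2, 0.5, 0.8\}$).
Gradient boosting fits staged trees on logistic loss (xgboost; depth
{2, 3}, rounds {50, 200}, learning rate {0.05, 0.1}). Grids are small by
design — enough to exercise selection without dominating runtime — and
exposed as arguments.

AUC is computed by the rank (Mann–Whitney) statistic with tied scores
counted ½, which equals brute-force pair counting (asserted exhaustively
in tests). Sensitivity and specificity are reported at the Youden-J
maximizing threshold by default (the lowest such threshold on ties), with
a fixed-0.5 rule available; the original analysis does not state its
threshold rule, so it is a config option rather than a constant.

## Importance scores and simple prediction scores

The sample-wise importance of feature $i$ for sample $j$ is
$|w_{ji}|$ — the magnitude of that sample's own coefficient. The
alternative $|w_{ji} x_{ji}|$ is available behind a switch
(`mode = "weight_x"`); we default to the bare weight because the
procedure is described as computed *from the weight vector*, and the
value-weighted variant changes the ranking only through the feature's
realized magnitude, which the ±1/z preprocessing already equalizes in
scale.

Per sample, the top $k = \max(1, \lceil 0.10\,d \rceil)$ features by
importance are "ranked" (ties broken by stable feature order; the ceiling
guarantees a non-empty ranking). A feature's **importance score** is the
fraction of samples in which it is ranked, so scores always sum to $k$
across features — a conservation law the tests assert. Features with
score ≥ 0.1 (strict `>=`) are extracted; each carries the sign of the
median of its sample-wise weights over the *discovery* cohort only
(validation data never influence model construction). Zero medians are
dropped with a warning rather than assigned an arbitrary sign.

The **simple prediction score** is $S_j = \sum_i \sigma_i x_{ji}$ over
the extracted features' *preprocessed* values. We read "original values"
as the preprocessed ±1/z-scale values rather than raw laboratory units:
published score ranges of a dozen-feature score (roughly −1.4 to 13.2)
are consistent with unit-scale inputs and incompatible with raw PSA in
ng/mL; a raw-value mode exists behind a switch.

**Quartiles.** Scores are ordered (ties by stable input order) and cut
into four contiguous groups whose sizes differ by at most one, computed on
the pooled discovery + validation scores, matching how the stratified
displays pool both cohorts. The quartile × response table is tested with
an uncorrected chi-square (df = 3); because the analysis could equally
have compared only the extreme quartiles, a Q1-vs-Q4 2 × 2 chi-square is
emitted alongside.

## Survival evaluation

Kaplan–Meier curves use the product-limit estimator; log-rank tests the
k-group null (chi-square, k − 1 df). Harrell's C is
$(\text{concordant} + \tfrac12\,\text{tied-score}) / \text{comparable}$,
where a pair is comparable when the earlier time is an event, tied times
are comparable only when exactly one member has the event (the censored
member counting as longer), and both-event or both-censored ties are not.
These are the standard Harrell rules; the implementation is checked
against exhaustive pair enumeration and against
`survival::concordance()`. Score orientation matters: a score oriented
"higher = better prognosis" must be negated before computing C
(`higher_risk = FALSE`), or C will land below 0.5 by construction.

## Cross-population effect of a signed SNP panel

For a SNP with signed coefficient $c \in \{\pm1\}$ and minor-allele
frequency $p$, the Hardy–Weinberg expected contribution to the score is
$c \cdot 2p(1-p) + 2c\,p^2$: heterozygotes (probability $2p(1-p)$) carry
$c$ once, minor homozygotes (probability $p^2$) twice. Algebraically this
is exactly $2cp$ — the coefficient times the expected minor-allele
count — an identity the tests assert on a dense grid and against
Monte-Carlo genotype simulation. The panel effect for a population is the
unrounded sum over SNPs with available frequencies (rounding to two
decimals only at display); SNPs without frequencies stay in the panel but
are excluded and counted. The coefficients are the ±1 simple-score signs,
not median weights — the only reading under which the published
population sums are reproducible.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes:
binary clinical features are Bernoulli (±1) with configurable prevalence,
quantitative features Gaussian with configurable mean/SD, genotypes
independent Hardy–Weinberg draws per SNP. The responder label is Bernoulli
with probability $\sigma(\beta_0 + \beta^\top z_j)$ on the preprocessed
scale; survival times for PFS/CSS/OS are exponential with log-hazard
proportional to the same linear predictor (baseline rates in the ratio
1 : 1/3 : 1/2, progression being the most frequent event), so a larger
predictor means stochastically shorter event times under the default
positive hazard coefficient. Censoring is independent and uniform over a
configurable horizon (default 5 years), applied with the configured
probability per sample — the simplest mechanism, since no censoring
process is described for the real cohort. Missingness is injected
completely at random into clinical features only, as genotypes are array
calls in the emulated design.

Subgroup heterogeneity — the regime that motivates per-sample weights —
is specified as two alternative effect vectors keyed either to an observed
binary feature (so the subgroup is inferable from $x$, and the PWL model
can beat any global linear model) or to a latent indicator (in which case
no model can beat chance pooled, but within-subgroup signal is strong;
the generator returns the indicator for exactly that kind of check).

The PSA-series generator constructs each series to satisfy or violate the
progression rule *by construction* — declining, sub-2.0, and sub-50 %-rise
failure modes — so the flagged fraction is exact, not a sampling outcome.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, population structure, genotyping error, informative censoring,
informative missingness, or the real marginal distributions of the
clinical covariates (which are not public). Passing tests therefore
demonstrate correctness of the procedures and their behavior under the
assumed generative structure, not predictive performance on real
patients; the published AUC/C-index values on the private cohort are
explicitly not reproduction targets.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: single-class labels, constant features,
non-finite feature values, all-censored survival data, empty extracted
feature sets. Ties are always broken deterministically (stable order), so
every result is a pure function of data, config and seed. The test suite
exercises the heavy simulation claims at the sizes the claims name —
n = 2000 cohorts for parameter recovery (3 true effects of ±1.5 among 30
features) and for the subgroup-flip heterogeneity advantage (10 seeds
each, majority criterion ≥ 8/10), 10^5 genotype draws for Hardy–Weinberg
calibration, and 1000 replicates for type-I error of the log-rank and
chi-square tests — while module tests use smaller configurations of the
same machinery.

## Known limitations

The original deep-unified-network topology, training schedule and the
precise sample-wise importance formula are not recoverable from the
method's published description; the concretizations above (dense
connectivity, Adam with early stopping, importance $=|w|$) are this
package's own, exposed as configuration where a defensible alternative
exists. The generator's clinical-feature distributions are plausible
defaults, not matched to the real cohort. Confidence intervals are
provided for no between-model contrasts; the C-index and AUC are point
estimates here.
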