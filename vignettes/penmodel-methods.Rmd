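---
title: "Methods: repeatability animal models with pen-based contemporary groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability animal models with pen-based contemporary groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A daily milk weight `y` of cow `i` at milking `m` on day `t` is modeled as

```
y = AFC_class + DIM_class + cg + a_i + pe_i + e
```

where AFC (age at first calving, six classes: up to 22, 23-24, 25-26,
27-28, 29-30, 31+ months) and DIM (days in milk, ten 30-day classes) are
fixed; `cg` is the contemporary group, either herd-year-season of calving
(HYS, one level per cow-lactation) or herd-pen-milking date (HPM, one
level per pen per day, so a cow visits many levels); `a` is the additive
genetic effect with `a ~ N(0, A sigma2_a)` over the pedigree; `pe` the
permanent environmental effect and `e` the residual, both iid normal.
The 305-day variant drops DIM and pe and uses one record per cow. All four
layouts are exposed as presets; for models 1-3 the contemporary group may
be fixed or random, model 4 is HYS-fixed plus HPM-random by construction.

Assumptions worth stating: homogeneous residual variance across herds and
lactation stages; no autocorrelated residual within cow (a possible
extension, deliberately out of scope); no genetic groups for unknown
parents; no genomic information.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `min_group` (edits) | 25 cows | minimum distinct cows per HYS and per HPM level; groups below it are removed iteratively until a fixed point, because each removal can shrink other groups |
| `n_iterations / burn_in / thin` | 50,000 / 10,000 / 10 | reference estimation protocol for production runs; desk-scale tests use 3,000-6,000 iterations with thin 5 |
| prior `nu, s2` per variance | `-2, 0` | flat on the variance, the customary improper default of animal-breeding Gibbs software; `nu = 0` gives the Jeffreys prior |
| `min_daughters` (PTA) | 10 | sire reliability is only reported with a minimally informative daughter group |

## Estimation

Location effects are sampled single-site from their full conditionals with
on-the-fly residual adjustment; no mixed-model equations are ever formed.
Levels of one factor partition the records, so a factor is refreshed in one
sweep (its levels are conditionally independent); the additive effects are
swept in pedigree order with the sparse `A^{-1}` (Henderson's rules with
inbreeding; inbreeding by the Meuwissen-Luo recursion) supplying the prior
coupling; variances are drawn from scaled-inverse-chi-square full
conditionals, the additive one from `a' A^{-1} a`. Fixed effects use flat
priors; the first fixed factor absorbs the intercept and each later fixed
factor has its first level constrained to zero (corner-point constraints —
contemporary-group contrasts are never interpreted, and variance components
and breeding values are invariant to the choice).

### The a/pe transfer update

With 100+ records per cow, the data pin down `a_i + pe_i` while the split
is informed only by relatives and the priors. Plain single-site sampling
then mixes the split — and with it `sigma2_a / sigma2_pe` — at a crawl: from
a cold start the additive sweep absorbs each cow's whole effect, `pe' pe`
collapses, and the chain needs tens of thousands of iterations to
equilibrate. The sampler therefore adds one scalar Gibbs update per
phenotyped cow on the reparameterized coordinate `delta` in
`(a_i + delta, pe_i - delta)`. The likelihood depends on the sum only, so

```
delta ~ N( (pe_i/sigma2_pe - (A^{-1}a)_i/sigma2_a) / P, 1/P ),
P = (A^{-1})_ii/sigma2_a + 1/sigma2_pe
```

— an ordinary Gibbs draw on a linear transformation, exact in distribution
(each such draw leaves the joint posterior invariant) and costing one
sparse row product. It is neither a blocked nor a collapsed update; it
simply adds a coordinate direction in which the chain can move freely.
Correctness of the whole sampler, including this move, is verified against
brute-force grid integration of the variance posterior on a 3-animal toy
system, against the least-squares closed form for a fixed-effects-only
model, and against ANOVA method-of-moments on a balanced one-way design.

A note on the closed-form oracle: the posterior mean of the residual
variance in a fixed-effects model equals `SSE/(n - p - 2)` under the
Jeffreys prior (`nu = 0`), not under the flat default (`nu = -2`, which
gives `SSE/(n - p - 4)`); the oracle tests therefore run with `nu = 0`
explicitly.

## Derived summaries

Heritability is computed both with the contemporary-group variance in the
denominator (`h2`) and without it (`h2*`); repeatability `r2` adds `pe` to
the numerator over the full denominator. Two estimators are reported for
each ratio: the plug-in ratio of posterior means, and the posterior mean of
the per-sample ratio (they differ by a Jensen gap; published tables do not
always say which was used, so both are first-class). Sire PTA is half the
posterior-mean additive effect, its PEV the variance of the PTA samples,
and `REL = 1 - PEV/sigma2_a` with the same run's posterior-mean additive
variance (a self-consistent base; no external genetic base is applied).
Monte-Carlo noise can push REL outside `[0, 1]` for weakly connected
sires; values are clipped with a warning.

## The synthetic world

`simulate_herds()` generates multi-herd populations of primiparous cows
milked up to 3 times daily: a two-generation pedigree (unrelated founder
sires and dams, sires with daughters across herds), calving dates uniform
over the configured span, season = calendar quarter, HYS effects iid, and a
pen-day effect following a stationary AR(1) within each pen. The lactation
shape is carried by the ten DIM class means directly (`dim_curve`), because
that is exactly the resolution the fitted models see. Default variance
components (10.85, 15.01, 14.60, 10.34, 4.96 kg^2 with lag-1 pen
autocorrelation 0.9) are sized like published daily-milk repeatability
analyses.

Pens are reassigned every 14 days (default). Under random reassignment the
pen process is exogenous: the expected correlation between breeding value
and experienced pen effect is zero — sorting cows by their *own* phenotype
cannot correlate them with the *destination* pen's exogenous process,
whatever the autocorrelation (the trailing mean conditions on the old pen,
not the new one). A positive genotype-environment correlation requires the
environment to respond to the ranking, which is also the realistic
mechanism: production-ranked pens are fed different rations. Under
`reassign_on_phenotype = TRUE` a configurable share (`pen_rank_share`,
default 0.25) of the pen-day variance is therefore a persistent
production-rank component; cows are re-penned by quantile of their trailing
7-day mean yield. The share is kept minor deliberately: field analyses
show HYS-based models remaining essentially unbiased even on pen-managed
farms, which bounds how much BV-correlated pen environment the real world
can contain.

What the generator does *not* emulate — so a green test does not establish
robustness to it: health events, dry-offs and culling, multiple parities,
heterogeneous residual variance, seasonal production waves, and the small
negative Gaussian tail of simulated milk weights (real weights are
nonnegative; the readers warn rather than reject, and the linear model is
kept exact).

## Data edits

Records beyond day 300 are dropped (the ten 30-day classes cover exactly
300 days; the 305-d projection scales the 300-day sum by 305/300 — the
source systems' exact projection is unpublished, so this linear stand-in is
declared, not inferred). An age of exactly 30 months falls in the 29-30
class, reading "30+" as "beyond the previous bin". The 25-cow minima are
enforced by iterating HPM-then-HYS removals to a fixed point; the fixed
point is order-invariant (property-tested against a brute-force rescan
oracle) and the operation is idempotent.

## Confounding: what reproduces and what does not

With phenotype-driven reassignment and autocorrelated pen effects, the
package reproduces the qualitative field pattern: fitting HPM as random
inflates the additive variance relative to HPM fixed, and adding a fixed
HYS alongside random HPM (model 4) pulls both `sigma2_a` and `sigma2_pe`
back toward the HYS-only values. One reported leg does **not** reproduce
at desk scale and its test is left deliberately red: the drop of
`sigma2_pe` under HPM-random below HPM-fixed. With the edit-enforced 25+
cows per pen-date, a group level can only absorb the *pen mean* of the
cows' permanent effects, not individual `pe`; in this simulator the
persistent pen process is instead absorbed into `pe` under every model-3
variant (cows keep near-static pen membership once sorted), so both
variants show elevated `sigma2_pe`. Reproducing the reported drop appears
to require the original data's scale and management churn, which the
synthetic world does not claim to match.

## Numerical choices and degenerate inputs

Chains are deterministic given a seed (R's RNG drives the compiled
sampler); bit-identity across platforms is not promised. Variance draws
guard against non-positive degrees of freedom (e.g. a flat prior with
fewer than three levels of a random factor is rejected by construction).
Empty simulations write valid header-only files; an edit pass that removes
everything is an error, not an empty dataset. Effective sample sizes use
Geyer's initial positive-sequence estimator; the early-vs-late location
diagnostic replaces spectral densities with ESS-adjusted standard errors
and flags |z| > 3; constant chains report `NA` diagnostics. Acceptance
tests scale the published protocol down (one milking/day, calving
concentrated in one year so instantaneous herd sizes match multi-hundred-
cow field herds, 3,000-6,000 iterations) and state so next to each test.

## Known limitations

Single-trait, single-parity, two-generation synthetic pedigrees (the
pedigree utilities themselves handle arbitrary depth, including 5-
generation truncation); no REML cross-check in-package; the HPM-random
`sigma2_pe` behavior above; REL is the simple PEV-based approximation, not
a daughter-equivalent or cross-validation reliability.
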