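---
title: "Models and methods in nmakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nmakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmakit)
```

nmakit synthesizes aggregate evidence from networks of randomized trials
in which most treatment comparisons are informed by a single study — the
situation typical of first-line metastatic castration-resistant prostate
cancer, where new regimens are trialled against one comparator each.
This vignette is the package's own account of the models it fits, the
numerical choices behind them, and what its synthetic-data tests do and
do not demonstrate.

## Contrast-level model for time-to-event outcomes

Treatment effects are modelled on the log hazard ratio scale with a
normal likelihood and identity link. Trial $i$ comparing treatment $k$
against its within-trial baseline $b(i)$ contributes

$$y_{ik} \sim \mathrm{Normal}(\delta_{ik},\ \mathrm{se}_{ik}^2),$$

with the reported squared standard error treated as known. Under the
fixed-effect model $\delta_{ik} = d_k - d_{b(i)}$; under random effects

$$\delta_{ik} \sim \mathrm{Normal}(d_k - d_{b(i)},\ \tau^2),$$

where the $d_k$ are basic parameters against the network reference
($d_{\mathrm{ref}} \equiv 0$) and $\tau$ is the between-trial SD, shared
across comparisons. Contrasts from a multi-arm trial share the standard
covariance $\tau^2/2$, implemented exactly through multivariate-normal
blocks in the sampler. At the likelihood level, contrasts of a multi-arm
trial are treated as independent — propagating the sampling correlation
of contrasts sharing a baseline arm requires the baseline arm's variance,
which published summaries usually omit — and the fit logs a note whenever
multi-arm trials are present so the analyst can judge the approximation.

Arm-level binary outcomes use a binomial likelihood with logit link:
$r_{ik} \sim \mathrm{Binomial}(p_{ik}, n_{ik})$,
$\mathrm{logit}(p_{ik}) = \mu_i + \delta_{ik}$, with one nuisance
baseline $\mu_i$ per trial and $\delta_{ik}$ as above on the log odds
ratio scale.

### Priors

* Treatment effects and trial baselines: $\mathrm{Normal}(0, 100^2)$ —
  vague on the log scale, following the standard technical-support-
  document choice; configurable through `nma_priors()`.
* Heterogeneity: $\tau^2 \sim \mathrm{LogNormal}(-3.95, 1.79^2)$, the
  published informative prior for pharmacological-vs-pharmacological
  comparisons on mortality/major-morbidity outcomes. The source notation
  gives the spread as "1.792", which this package reads as $1.79^2$ (a
  squared SD whose exponent lost its superscript), since the prior family
  is defined by a mean and SD of $\log \tau^2$. Both numbers are
  overridable (`tau2_lognormal`), and a prior-only run of the sampler
  reproduces the stated distribution (tested).

With a single trial and a vague prior the posterior essentially equals
the likelihood, which is one of the unit-level checks.

### Sampling

The sampler is a blocked Gibbs scheme written for this model family
rather than a generic MCMC engine:

* **Fixed-effect normal model.** The posterior of $d$ is exactly
  multivariate normal (conjugacy of normal likelihood and prior), so
  draws are independent; chains exist only to feed the same diagnostics
  pipeline as the other models.
* **Random-effects normal model.** $\delta \mid d, \tau$ and
  $d \mid \delta, \tau$ are conjugate normal updates (two-arm trials
  vectorized, multi-arm trials as small matrix blocks; the $d$-update
  reuses a one-off eigendecomposition of the design cross-product).
  $\phi = \log \tau^2$ takes an adaptive random-walk Metropolis step,
  tuned toward a 0.44 acceptance rate in batches of 50 during burn-in
  and frozen afterwards, so the post-burn-in chain is a valid
  fixed-kernel Markov chain.
* **Binomial models.** Trial baselines (and, under random effects, the
  trial-specific $\delta$) are conditionally independent across trials
  given the rest, so their Metropolis updates are proposed and
  accepted/rejected vectorized per trial; $d \mid \delta, \tau$ remains
  conjugate under random effects, and fixed-effect $d$ uses
  coordinate-wise adaptive Metropolis.

Defaults follow the analysis plan: 4 chains, 60 000 burn-in and 60 000
sampling iterations, thinning 1. Starting values are dispersed
($d \sim \mathrm{Normal}(0,1)$ per chain, $\phi$ drawn from its prior and
clamped to $[-8, 1]$), and every chain's stream derives deterministically
from the master seed, so results are bit-reproducible for a fixed
(seed, chains, schedule) triple.

### Diagnostics and model fit

Convergence uses rank-normalized split R-hat (the larger of the bulk and
folded statistics) with bulk ESS on the rank-normalized draws and tail
ESS as the smaller ESS of the 5% and 95% quantile indicators;
autocorrelations are summed under Geyer's initial monotone positive
sequence. The gate — all R-hat < 1.05, both ESS > 400 — mirrors the
analysis plan; a failing fit is returned but flagged, and the pipeline
marks the outcome `failed-diagnostics` rather than discarding it.

Absolute fit is the posterior mean residual deviance compared with the
number of unconstrained data points (each contrast or arm contributes
$((y-\delta)/\mathrm{se})^2$, or the binomial saturated-model deviance);
relative fit is DIC with $p_D$ computed by plugging the posterior mean
fitted values into the deviance.

## Rankings

Each posterior draw orders treatments in the declared benefit direction
(hazard-type outcomes: lower is better; response odds: higher is
better). Ties — which have probability zero for continuous posteriors but
occur in degenerate test cases — are broken by adding seeded uniform
noise at $10^{-12}$, far below any meaningful effect difference, which
makes direction reversal map ranks exactly onto their mirror image
(so $\mathrm{SUCRA} \mapsto 1-\mathrm{SUCRA}$ exactly, a tested
identity). SUCRA is
$\sum_{j=1}^{a-1} P(\mathrm{rank} \le j) / (a-1)$; league tables are
ordered by descending SUCRA, and all pairwise summaries are computed on
the log scale before exponentiation so reciprocal cells are exact.

## Consistency

Inconsistency is assessed by node-splitting, the standard
direct-versus-indirect contrast: the analysis plan asserts that
inconsistency was assessed without naming a method in the main text, and
node-splitting is the established choice that produces a per-comparison
p-value. A comparison is splittable when at least one two-arm trial
compares the pair directly and the remaining evidence still connects the
two treatments. The refit gives the direct evidence its own parameter
$\omega$; the reported p-value is
$2\min\{P(\omega - d_{\mathrm{ind}} > 0), P(\omega - d_{\mathrm{ind}} < 0)\}$.
Multi-arm trials containing the pair stay in the network parameterization
(splitting them would break their internal correlation structure); no
data are dropped. Under consistent simulation the p-values are
approximately uniform (tested by Kolmogorov–Smirnov over replicated
triangles).

## Kaplan–Meier reconstruction

For trials reporting only a KM figure, pseudo individual-patient data are
rebuilt from digitized click points and the number-at-risk table. Within
each interval between consecutive risk-table times, the censor count is
adjusted iteratively until the implied number at risk at the interval end
matches the published value; censor times are spread evenly across the
interval, and event counts at each click point are chosen so the running
product-limit estimate tracks the digitized survival. Numerical
conventions, fixed after hand-tracing small cases:

* A survival drop at exactly a risk-table time belongs to the interval
  ending there (the published count already reflects it). This makes the
  two-patient example — curve dropping to 0.5 at the single risk time —
  reconstruct to exactly one event.
* Event counts round half away from zero; digitization noise that makes
  survival increase by up to $10^{-6}$ is clamped flat, larger increases
  are errors.
* Patients still at risk after the last click are censored there.
* When a total event count is reported, the constrained variant
  re-balances final-interval censorings against events until the total
  matches.

The hazard ratio is then estimated by the two-group Cox partial
likelihood with Efron tie handling (reconstruction creates heavy ties at
click times), Newton–Raphson with step tolerance $10^{-8}$, SE from the
inverse observed information. Monotone likelihoods — all events drifting
to one arm — are detected and fall back to the Firth-penalized estimate
with a warning. The solver matches `survival::coxph` to three decimals
on large simulations and a direct partial-likelihood maximizer to
$10^{-4}$ on four-patient toys (both tested).

## Penalized-likelihood safety model

Safety outcomes are rare, follow-up differs across trials, and more
follow-up means more events, so adverse events use a fixed-effect
binomial model with complementary log-log link and log follow-up offset:

$$\mathrm{cloglog}(p_{ik}) = \ln f_i + \mu_i + (d_k - d_{b(i)}),$$

whose $\exp(d)$ are discrete hazard ratios (for exponential event times
this is exact: $\mathrm{cloglog}(p) = \ln f + \ln(\text{rate})$, so
doubling follow-up while halving rates leaves $d$ unchanged — a tested
invariant). Fixed-effect only, matching the stated analysis policy for
safety outcomes. Estimation is Fisher scoring on the likelihood plus,
by default, the Firth/Jeffreys penalty $\tfrac12 \ln\det I(\theta)$: the
cited penalized-likelihood method is built to de-bias rare-event
estimates, and plain Firth is the canonical such penalty; since the
source's exact tuning is not restated, the penalty has an off switch
(`penalty = "none"`), in which case the fit matches an independent
cloglog GLM with offset to four decimals (tested). The penalty gradient
uses the analytic weighted-leverage form
$\tfrac12 \sum_i h_i (\partial \log w_i / \partial \eta_i) x_{ij}$.
Missing follow-up is imputed with the across-trial median, logged.

## Synthetic evidence and what the tests show

The generators emulate: sparse star-plus-chord network topologies (most
comparisons single-trial, as in the motivating evidence base, with a
guaranteed single-trial leaf treatment for sensitivity analyses);
normally distributed between-trial heterogeneity; binomial response and
rare-event counts; exponential survival with administrative censoring,
"digitized" by sampling the trial's own KM estimate on a click grid with
a coarser risk table. Fixture factories reproduce the published network
dimensions (13 trials/14 treatments, 20/18, 26/25, 7/6, 12/11). One
master seed drives every draw through per-component substreams, so
adding a generator never perturbs existing output.

They deliberately do not emulate: non-proportional hazards, patient-level
covariates or effect modifiers (so exchangeability holds by construction),
reporting heterogeneity, or digitization error beyond grid resolution.
Passing tests therefore demonstrate correctness of the estimators under
the stated models — not robustness to the cross-trial heterogeneity and
assumption violations that a real evidence base may carry.

Problem sizes used by the test-suite studies, chosen to estimate each
property with useful precision: coverage/bias over 20 replicate networks
of 12 trials and 5 treatments at $\tau = 0.2$ with a 10 000/10 000
schedule; rare-event bias over 200 replicate 12-trial networks at ~1%
event probability; node-split calibration over 200 consistent triangles;
and the full 60 000/60 000 default schedule on the 20-trial/18-treatment
fixture for the convergence gates.

## Design choices on open points

* **Reference treatment**: configurable; defaults to a
  placebo/best-supportive-care-style node when present, else the
  lexicographically first treatment. Basic-parameter orientation does not
  affect pairwise summaries.
* **Multi-arm trials** are kept as single trials contributing all
  contrasts against their declared baseline arm, never split into
  independent two-arm trials (which would double-count the baseline arm).
* **Disconnected trials** are excluded with a logged warning rather than
  aborting the run, matching the workflow of dropping non-connecting
  studies at feasibility.
* **Node identity** is by exact regimen token, so dose variants are
  distinct nodes; node merges are configuration, not code.
* **Zero-cell odds ratios** add 0.5 to all four cells (Gart correction)
  exactly when a cell is zero; percent-derived counts round half away
  from zero. Both rules are stated because the source leaves them
  unstated.
* **When both an HR with CI and a KM figure exist**, the reported HR
  wins, consistent with preferential extraction of published estimates.

## Limitations

Credible intervals inherit the aggregate-data assumptions: no adjustment
for effect modifiers, no meta-regression, and likelihood-level
independence of multi-arm contrasts (above). The binomial samplers use
random-walk updates whose mixing degrades on very large, very sparse
response networks — the convergence gates exist to catch this. The
penalized-likelihood model is fixed-effect by design and does not
estimate heterogeneity for safety outcomes.
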