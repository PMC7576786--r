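---
title: "Methods: coral-reef dependence of fishery catch and overfishing risk under productivity declines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coral-reef dependence of fishery catch and overfishing risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdep)
```

`reefdep` answers two linked questions about a tropical fishery
jurisdiction. First, *how much of the catch depends on coral reefs?* —
answered by an ordinal habitat classification of fished taxa and a
composition analysis of logbook catch by gear, region and sector. Second,
*what does that dependence imply if reef degradation cuts stock
productivity?* — answered by fitting a Bayesian surplus-production model
to catch-per-unit-effort (CPUE) series of reef-dependent stocks and
converting the posterior into a risk-of-overfishing curve under sudden
declines in the intrinsic growth rate.

All stages run on synthetic inputs with known ground truth, so the whole
pipeline is testable end to end without access to any fisheries data
portal.

## The coral-dependence classification

Each fished species carries structured evidence rows (`habitat_evidence()`)
recording life stage, observation method, substrate, and three boolean
flags forming a strict hierarchy: obligate live-coral dependence implies
live-coral dependence, which implies coral-reef association.
`classify_species()` maps evidence to an ordinal category:

1. not known to be associated with coral reefs (live or dead);
2. associated with coral reefs but not known to depend on live coral;
3. documented dependence on live coral cover;
4. obligate dependence on live coral cover.

The rule is a maximum over evidence rows: a species is category 3 only if
some row carries specific live-coral-dependence evidence; reef association
alone never exceeds category 2. Two consequences are deliberate and
tested. *Monotonicity*: adding evidence can never lower a category, which
is how conflicting studies are reconciled (the literature does not say how
conflicts were resolved in curated databases of this kind; the maximum is
our conservative choice, not a reading). *Life-stage neutrality*: evidence
from any life stage counts toward the species label, because recruitment
evidence from juveniles is exactly the kind of dependence the scheme is
meant to capture.

Catch statistics often report genus-, family- or market-level groups.
`classify_group()` assigns a group the highest category among its members
— a butterflyfish family group containing one obligate coral feeder is
category 4 even though many members are not. `build_catalog()` resolves
every catch label through member evidence, explicit overrides (used for
taxa classified from external global assessments, or fixed rules such as
harvested live coral = category 4), and routes unresolvable labels (e.g. a
bare "fish" group) to a rejects table instead of silently defaulting them.

`coverage_rank()` implements the review-scoping rule: taxa are ranked by
catch and the shortest prefix reaching 95% of cumulative weight (ties
broken lexicographically; a prefix hitting exactly 95% qualifies) defines
the set needing habitat review.

## Catch-composition profiles

`aggregate_profile()` converts catch records to mean annual quantity per
grouping key and category over an analysis window, then to percent shares.
Three semantics matter:

- **Zero-fill.** A taxon absent from a year's logbook contributed zero
  catch that year; the annual mean always divides by the full window
  length. Treating absence as missing would silently inflate means.
- **Basis separation.** Weight-based records (commercial and charter
  logbooks, tonnes) and count-based records (recreational and aquarium
  surveys, individuals) are never mixed in one aggregation; the function
  refuses mixed bases rather than warn.
- **Conservation.** Unclassifiable taxa accumulate in an explicit
  `excluded_quantity`; excluded plus categorized quantity always equals
  the total input, and category 4 is always carried as a column so "no
  catch in the obligate category" is a reportable zero.

## Regression of catch share on reef area

For each category, the percent of regional catch in that category is
regressed on the percent coral-reef area of the region:
$y_i \sim \mathrm{Normal}(\alpha + \beta x_i,\ \sigma^2)$, with broad
default priors: effectively flat intercept (Normal with variance $10^8$, a
proper stand-in for the improper flat prior), $\beta \sim
\mathrm{Normal}(0, 1000)$, and a log-gamma prior on the precision
$\tau = 1/\sigma^2$ with shape 1 and rate $5\times10^{-5}$. Percentages
(0–100), not proportions, enter the model on both sides; slope magnitudes
are then in percentage points per percentage point.

Under these priors every full conditional is conjugate — Gaussian for
$\alpha$ and $\beta$, Gamma for $\tau$ — so `fit_linear_model()` uses a
pure Gibbs sampler: exact conditional draws, no proposal tuning, and
mixing that a random-walk step could only approximate. Four chains run
from dispersed starts; fits are rejected unless split R-hat < 1.05 for
every parameter and the slope's effective sample size reaches 400.
Reported summaries are the posterior median slope, central 95% credible
interval, and $P(\beta > 0)$ / $P(\beta < 0)$ as the fraction of draws
strictly on each side of zero. Each category is fitted separately; we do
not impose a compositional (logit-ratio) transform because the quantity of
interest is the raw percentage relationship.

## The surplus-production model

Biomass dynamics are Schaefer (logistic):
$$B_1 = \psi K, \qquad B_{t+1} = B_t + r B_t\left(1 - \frac{B_t}{K}\right) - C_t,$$
with catch $C_t$ known and complete. MSY is $rK/4$, attained at $B = K/2$.
The observation model is lognormal CPUE around catchability times biomass,

$$\mathrm{CPUE}_t = q(t)\, B_t\, e^{\varepsilon_t}, \qquad
\varepsilon_t \sim \mathrm{Normal}(0, \sigma_{\mathrm{obs}}^2),$$

where $q(t)$ switches from $q_{\text{pre}}$ to $q_{\text{post}}$ at a
configured regime year (years strictly before the regime year use the pre
value), representing a management restructure that changed fleet
efficiency; the default regime year in the pipeline is 2004. An optional
efficiency trend multiplies $q(t)$ by $(1+p/100)^{t-t_1}$ from the first
data year, modelling technological drift (the conventional sensitivity
value is 1%/yr). Estimation is observation-error-only: the trajectory is
deterministic given $(r, K, \psi)$ and catch. A process-error flag exists
in the simulator — not the fitted model — to probe robustness.

### Priors

- $r \sim \mathrm{lognormal}(\log 0.3,\ 0.5^2)$ — centred on a moderately
  productive demersal stock, wide enough to cover 0.1–0.9/yr.
- $K \sim \mathrm{lognormal}(\log(5 \times \max C),\ 1^2)$ — anchored to
  the observed catch scale at fit time.
- $q_{\text{pre}}, q_{\text{post}}$: flat on the log scale (scale
  parameters; improper but harmless given informative CPUE).
- $\sigma_{\mathrm{obs}} \sim \text{half-Normal}(0.3)$.
- $\psi \sim \mathrm{Uniform}(0.2, 1.1)$. The upper bound deliberately
  sits *above* 1: for series that begin with an effectively unfished
  stock, a bound at exactly 1 pins the posterior against the boundary and
  biases derived depletion downward. In calibration runs (20 simulated
  stocks, truth $\psi = 1$) the bounded prior produced one-sided coverage
  failures of the 95% depletion interval; allowing initial biomass up to
  10% above deterministic carrying capacity — a standard allowance, since
  real stocks fluctuate around $K$ — restored nominal coverage without
  touching any data-generating setting.

### Sampling and diagnostics

`fit_spm()` runs adaptive random-walk Metropolis on the log-transformed
parameter vector (logit-transformed for $\psi$), four chains from
dispersed starts. During warmup the proposal scale is tuned by
Robbins–Monro toward an acceptance rate of 0.25 and the proposal
covariance is refreshed every 100 iterations from the recent history;
adaptation freezes at the end of warmup. Defaults are 3000 warmup + 3000
retained draws per chain. Convergence is gated on split R-hat < 1.05 and
total effective sample size ≥ 400 for every parameter; a failed gate
doubles the run length (up to twice) before raising an error that carries
the diagnostics. Each retained draw yields derived MSY ($rK/4$, an exact
identity audited in the tests) and final-year depletion $B_T/K$ by
re-projecting the trajectory. Goodness of fit is reported as the squared
Pearson correlation between observed and posterior-median predicted CPUE,
both on the log scale (the scale on which the error model is additive).

### Numerical choices

Trajectories are floored at $10^{-6} K$ and flagged; the likelihood
assigns flagged trajectories $-\infty$ rather than letting the floor
distort gradients silently. The biomass update is evaluated as
$B + (g - C)$ (net change grouped first) so that the MSY equilibrium
$g = C$ cancels exactly in floating point — the equilibrium identities in
the test suite are bitwise, not approximate. CPUE gaps are skipped in the
likelihood; catch must be complete because the trajectory depends on it.

## Risk of overfishing under productivity decline

Reef degradation is represented as a sudden reduction of the intrinsic
growth rate by $p\%$ — recruitment of reef-associated fish depends on
reef structure, so habitat loss maps naturally onto $r$, leaving $K$
untouched. For each posterior draw, the reduced reference point is
$\mathrm{MSY}_p = r(1 - p/100)K/4$, and `risk_curve()` reports, for every
integer $p$ from 0 to 100, the fraction of draws whose $\mathrm{MSY}_p$ is
strictly exceeded by the mean catch over a recent window (default: the
last three data years; for the motivating application, 2016–2018).
Computing the exceedance per draw — rather than at posterior medians — is
the proper Bayesian reading of "probability that catch exceeds MSY".
Strict inequality means ties count as not-overfishing; ties have measure
zero under continuous posteriors. The curve is non-decreasing by
construction (each draw's indicator is monotone in $p$), equals the
posterior probability that current catch exceeds MSY at $p = 0$, and
equals 1 at $p = 100$ whenever recent catch is positive.

## What the synthetic data emulate — and what they do not

`sim_config()` defaults describe the commercial-catch setting the package
was built around: 57 species/groups, 9 reporting regions, a 10-year
window starting 2008, and a reef-area effect of 2.1 percentage points of
category-3 catch share per percentage point of reef area. Category
probabilities default to (0.50, 0.25, 0.15, 0.10) so that all four
categories, including the aquarium-fishery obligate class, are represented
in the evidence database. Species are apportioned to categories by largest
remainder and then shuffled under the seed, guaranteeing representation
of every category with appreciable probability — an iid draw could leave a
category empty and make the share targets unattainable. Catch-cell noise
is lognormal with configurable CV (default 0.1, a realistic magnitude for
region-by-taxon aggregates of logbook data), applied per taxon × region ×
year cell with mean 1 so expected shares equal their targets.

`spm_sim_config()` defaults to a 40-year series ending 2018 with
$r = 0.3$, $K = 5000$ t, $\sigma_{\mathrm{obs}} = 0.05$ and an `up_down`
harvest pattern (harvest rate ramps from $0.05r$ to $0.75r$ at 60% of the
series, then back down to $0.25r$). The rise-then-fall contrast is the
default because one-way effort histories leave $r$ and $K$ weakly
identified — parameter-recovery testing needs a depletion-and-rebuild
signal. Configurations that would push simulated biomass below
$10^{-3}K$ are rejected with the offending year named, keeping simulated
data inside the fitted model's support.

What the generators do *not* emulate: CPUE standardization (the simulator
emits an already-standardized index; real logbook CPUE needs
standardization before it meets this model), taxonomic mislabelling,
regional differences in total catch scale, spatial structure within
regions, multispecies interactions, and recreational catch missing from
the dynamic analysis. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generating model — not that
real QFish-style extracts would yield the same certainty.

## Problem sizes and reproducibility

The test suite fits 20 simulated stocks for the recovery study (40-year
series, four chains each), one regime-change stock, 50 regression
replicates for slope-coverage, and 200-case property sweeps for the
composition laws; these sizes give stable pass/fail behaviour at
single-digit-minute runtimes. Every generator call takes one master seed
and derives its sub-streams deterministically, so all outputs are
bit-reproducible; the pipeline writes a `run_info.csv` sidecar with the
package version and seeds so reruns are attributable.

## Known limitations

- The Schaefer form is fixed; no Fox or Pella–Tomlinson shape parameter,
  no age structure, and no recruitment–spawning time lags, so productivity
  responses that act through delayed recruitment appear here only as an
  instantaneous change in $r$.
- The risk metric compares recent catch to a reduced reference point; it
  does not re-project biomass under the reduced $r$, and so understates
  risks that compound over time.
- Observation-error-only estimation attributes all CPUE variance to
  observation noise; strong process variability would widen true
  uncertainty beyond the reported intervals (the simulator's
  process-error flag exists to explore exactly this).
- The regression treats regional shares as independent Gaussian
  observations; no spatial correlation structure is modelled.

## A minimal worked run

```{r, eval = FALSE}
out <- run_pipeline(tempfile("reefdep-run-"),
                    config = sim_config(seed = 7),
                    spm_config = spm_sim_config(seed = 7))
out$regression[, c("category", "median_slope", "p_slope_positive")]
depletion_summary(out$posterior)
head(out$risk_curve)
```
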