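---
title: "Evaluating drug-combination metrics with combobench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating drug-combination metrics with combobench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combobench)
```

## The problem

Two-drug checkerboard assays are routinely summarised by a single synergy
index, most often a Bliss-independence deviation ("Bliss volume") or the
Chou–Talalay Combination Index (CI).  Both indices, however, respond not
only to genuine pharmacological interaction but also to the *shape* of the
single-agent dose-response curves — most strongly to the product of the two
Hill slopes — and to experimental conditions such as noise and incomplete
maximal effects.  combobench provides (i) reference response-surface models
and simulators to quantify these biases by Monte-Carlo, (ii) the BRAID
parametric response surface, whose interaction parameter $\kappa$ is
designed to be shape-independent, and (iii) a screen-analysis layer that
asks which metric best recovers drug mechanism of action from a large
combination screen.

## Models

**Hill curve.** Each single agent follows the log-logistic curve
$E(d) = E_0 + (E_f - E_0)\,x/(1+x)$ with $x = (d/ID_M)^n$.  Two fitting
routes are provided, matching the two CI traditions: the median-effect
linearisation (`fit_hill_median_effect`, responses clipped into
[0.5%, 99.5%] and logit-regressed on log dose, bounds fixed at 0/100%) and
direct nonlinear least squares (`fit_hill_ls`, Levenberg–Marquardt, bounds
free or fixed).

**Loewe / URSA additivity.** The non-interacting reference surface solves
$d_A/IC_{E,A} + d_B/IC_{E,B} = 1$ (`loewe_effect`).  With equal Hill
slopes this has a closed form; otherwise the monotone implicit equation is
solved by Brent's method to a residual below $10^{-9}$.  Agents with
unequal maximal effects are handled by *asymptotic additivity*
(`asymptotic_additive_effect`): the smaller-span agent's dose is mapped to
the dose that would produce the same effect if it shared the stronger
agent's maximal effect,
$D'_B = ID_{M,B}\left(\frac{R\,x}{1+(1-R)\,x}\right)^{1/n_b}$ with
$R$ the span ratio, and plain Loewe additivity is applied to the
transformed pair.  The transform is constructed so that both axis
marginals are preserved exactly.

**Bliss independence.** Survival probabilities multiply:
$S(d_A,d_B) = S_A(d_A)S_B(d_B)$.  Crucially, a Loewe-additive sham
combination does *not* satisfy Bliss independence: on the standard
10×10 two-fold checkerboard (max 32 µM) the mean deviation of an additive
self-combination from the Bliss prediction is about −10.3 percentage
points at Hill slope 0.5, −2.9 at slope 1, and +2.8 at slope 4.  This
slope-dependent offset, not interaction, is what a calibrated Bliss screen
largely measures.

**BRAID.** The parametric combined-action surface
$E = E_0 + (E_f - E_0)\,\tilde D^{h}/(1+\tilde D^{h})$, where
$h=\sqrt{n_a n_b}$,
$\tilde D = \tilde D_A + \tilde D_B + \kappa\sqrt{\tilde D_A \tilde D_B}$
and each $\tilde D_X$ is a span-weighted normalised dose (see
`?braid_params`).  $\kappa = 0$ is additive (identical to the
asymptotic-additive reference when the slopes match), $\kappa > 0$
synergy, $-2 < \kappa < 0$ antagonism.  `fit_braid` estimates all eight
parameters by Levenberg–Marquardt on transformed coordinates (log doses
and slopes, $\log(\kappa + 2)$), initialised from Hill fits of the two
axes with $\kappa$ starting at its neutral value 0.  The 95% interval on
$\kappa$ is a seeded *wild* residual bootstrap (sign-flipped residuals,
percentile interval, 200 resamples by default): sign-flipping keeps each
well's own residual magnitude, which matters because log-normal dosing
error makes the effective response noise much larger in the steep
transition region of a high-slope surface than elsewhere — an i.i.d.
residual shuffle understates $\kappa$ uncertainty there and inflates
false interaction calls above their nominal rate.  A surface is called
synergistic/antagonistic only when the interval excludes 0.  For clonogenic (colony-count) data,
`fit_braid_poisson` uses the same surface as a model of log plating
efficiency and maximises the Poisson likelihood with the seeding density
as exposure; its $\kappa$ interval is a parametric bootstrap, which is the
natural resampling scheme for counts.

**IAE.** The index of achievable efficacy summarises a fitted surface as
the ratio of the tested dose-space area $[0,D_A^{max}]\times[0,D_B^{max}]$
to the area failing an efficacy threshold, evaluated on a 201×201 linear
grid (`compute_iae`).  IAE is 1 when the threshold is never reached,
increases with both potency and synergy, and is invariant to rescaling
the dose axes.  This area-ratio definition is this package's
self-consistent operationalisation of the published idea; all downstream
analyses depend only on its monotonicity properties and on `log10(IAE)`
differences, which are unchanged by the normalisation.

## The bias pipelines

`run_bliss_screen_sim` simulates whole Bliss screens: eight compounds that
differ only in Hill slope (0.5–4), thresholds calibrated per screen from
the 2.5/97.5 percentiles of 24 triplicate self-vs-self Bliss volumes, then
all 64 ordered combinations classified.  With the full calibration set the
band is wide and self-combinations stay inside it ~95% of the time, but
combinations of *unlike* slopes are still misjudged; with a low-slope-only
calibration, additive high-slope combinations are called synergistic more
than half the time, and with a high-slope-only calibration, low-slope
combinations are called antagonistic over 90% of the time.

`run_ci_condition_sim` evaluates both CI variants on triplicate additive
experiments (7.5% noise, ~10% log-normal dosing error) across twelve
pharmacological conditions — matched slopes 1–4, slope ratios 1.5–4
(pairs 1/1.5, 0.9/1.8, 0.8/2.4, 0.75/3), and partial maximal effects
90–60% — scoring seven constant-ratio diagonals at the 50% and 99% effect
levels with the conventional 0.5/2 cutoffs.  `run_braid_condition_sim`
runs the BRAID interval judgment on the same kind of surfaces; its false
calls are roughly symmetric and stay at or below ~10% per side in every
condition, which is the method's headline robustness property.

On dosing error: the intended concentration error is a ~10% pipetting
spread, i.e. a log-normal with $\sigma_{\ln} = \ln(1.1) \approx 0.0953$;
`noise_spec` exposes this as a parameter.

## The synthetic screen and what it does (and does not) emulate

`generate_synthetic_screen` produces a screen shaped like the large
public oncology combination screens: every drug pair in a 4×4
checkerboard (two replicates) plus replicated single-agent ladders,
across a cell-line panel, as fractional viability with 5% Gaussian noise.
Planted structure, with defaults chosen once to represent a realistic
screen:

* **Mechanism classes and potency covariation.** 16 drugs in 4 classes;
  each class has a latent per-cell-line sensitivity profile and a drug's
  log10 potency correlates 0.9 with its class profile (spread 0.3 log10
  units).
* **Interaction structure.** Pairwise $\kappa$ depends on the two
  classes through a fixed signed matrix (plus per-experiment jitter,
  sd 0.25).  Classes 1 and 2 deliberately share an identical interaction
  signature: interaction alone cannot resolve them, while potency can —
  the situation observed in real screens, where efficacy-based
  clustering resolves more mechanism classes than interaction alone.
* **Slope heterogeneity.** Hill slopes are drawn per drug (0.5–4),
  independent of class, with additional log-normal per-cell-line
  variation (sd 0.5).  Because the Bliss deviation of an additive
  surface is a strong function of the slope product, this injects
  mechanism-free structure into Bliss profiles — the screen-scale
  manifestation of the simulation biases.
* **Partial maximal effects** (per-drug maximal kill 0.75–1) and,
  optionally, near-inactive compounds (10% kill) for the activity filter
  and the null-compound similarity correction.
* **Expression coupling.** A small set of genes is linearly coupled to
  the class-1 sensitivity profile; the rest are noise.

Not emulated: plate-layout artifacts, batch effects, non-Gaussian noise,
shared wells between single-agent and combination series, and any real
compound identities.  Consequently, passing the screen-analysis tests
shows that the pipeline recovers planted structure under idealised noise,
not that it would rank metrics identically on any particular real screen.

## Screen analytics

`compute_metric_table` fits every (pair, cell line) combination with the
BRAID surface (baseline held at viability 1, since screen responses are
normalised), and derives $\kappa$, log10 IAE (limits at the highest
tested combination concentrations, threshold 0.5 survival), the Bliss
volume from 2-parameter viability-constrained Hill fits, the CI at 50%
viability from the checkerboard's main diagonal, Hill slopes and potency
indices (floored at 1 when 50% viability is not reached in range).
$\kappa$ estimates that peg the optimizer bounds or exceed $|\kappa|=15$
— an order of magnitude beyond the strongest interactions reported in
real screens — are recorded as `NA` with the row flagged: they arise when
one agent is essentially inactive in-range, and a single unbounded value
would otherwise dominate cosine profile similarity.

Profile similarity follows the conventions of the field: cosine for
signed interaction metrics (Bliss, CI, $\kappa$), Pearson on logs for
potency, and for IAE, Pearson minus a *null-compound correction* — the
mean correlation of each compound's IAE profile with the profile implied
by partner single-agent activity alone.  Without the correction, two
inactive compounds look almost identical because their combination
efficacy is entirely partner-driven.  Clustering is greedy agglomeration
maximising average pairwise similarity (ties broken lexicographically),
and agreement with a mechanism classification is the mean adjusted Rand
index over all partition levels.

On the generator's standard regime, IAE-based clustering scores highest
(it sees both potency and interaction), $\kappa$ next (it cannot separate
the shared-signature classes), and Bliss lowest (its profiles are
contaminated by slope structure).  The margins between adjacent metrics
are modest relative to the seed-to-seed spread of mean ARI — the ordering
is the typical outcome, not a per-draw certainty — so the packaged checks
average two fixed-seed screens; on isolated draws Bliss can approach
$\kappa$'s structural ceiling.

`relative_sensitivity` contrasts two anchor drugs per cell line as the
mean matched difference of log10 IAE (a value of +1 means the second
anchor's combinations are uniformly 10-fold more efficacious), and
`phenotype_projection` maps every cell line onto the axis defined by an
isogenic reference pair, anchored at 0 (feature intact) and 1 (feature
lost); coordinates beyond 1 indicate a "hyper-deficient" phenotype.
`rank_expression_association` ranks genes by the magnitude of the linear
coefficient of expression on a sensitivity score, which avoids rewarding
small noisy expression changes that correlate by chance.

## Numerical choices and degenerate inputs

* Loewe implicit solves: closed form for equal slopes, otherwise Brent
  with residual tolerance $10^{-9}$; doses of zero short-circuit to the
  axis marginals.
* `fit_hill_ls` initialises $ID_M$ at the dose whose response is nearest
  the half-span level with slope 1; constant-response data are returned
  flagged `flat` rather than fitted.
* `fit_braid` seeds from axis Hill fits, starts $\kappa$ at 0, bounds
  slopes to [0.02, 50] and log-doses to ±4 decades around the tested
  range; fits with $R^2 < 0.2$ are flagged low-information.  Bootstrap
  refits start from the full-data optimum.
* CI values are `NA` (excluded from tallies, never imputed) when any
  curve cannot reach the requested level.
* Boundary classification values (Bliss volume at a threshold, CI at
  exactly 0.5 or 2, $\kappa$ interval touching 0) are additive.

## Problem sizes in the packaged checks

The packaged tests and the acceptance script run the pipelines at
reduced but statistically meaningful scale: 40–50 repetitions for the
self-vs-self deviations, 200 screens for the calibration-bias rates, 100
simulations × 100 bootstrap resamples per pharmacological condition for
the BRAID false-call ceiling, and two 16-drug screens for the clustering
comparison.  The pipeline functions default to the full published scale
(1000 screens/simulations, 200 resamples) for users who want it.

## Limitations

The asymptotic-additive reference and the BRAID $\kappa=0$ surface
coincide exactly only for matched Hill slopes; for strongly differing
slopes they are close but not identical non-interaction references, which
is one reason the BRAID false-call rate is bounded by ~10% rather than
the nominal 5% in the differing-slope conditions.  The IAE area-ratio
normalisation is a package-level definition; absolute IAE values are not
comparable across dose-space limits, only within a fixed design.  All
screen-level conclusions are demonstrated on synthetic screens; the
analytics accept real screen tables (`read_screen_csv`) but no real data
ships with the package.
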