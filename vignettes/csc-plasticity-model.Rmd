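---
title: "Modelling cancer stem cell plasticity under hypoxia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cancer stem cell plasticity under hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscplasticity)
```

## The model

Breast cancer cell populations contain a small subpopulation of stem-like
cells (CSCs, identified here by the surface marker GD2) that interconverts
with the non-stem bulk. `cscplasticity` implements the minimal two-compartment
description of this plasticity: stem-like cells $S$ and differentiated cells
$D$, each dividing, dying and switching phenotype at first-order rates
(per day),

$$\frac{dS}{dt} = (\alpha_S - \delta_S)S - k_{SD}S + k_{DS}(t)\,D, \qquad
\frac{dD}{dt} = (\alpha_D - \delta_D)D - k_{DS}(t)\,D + k_{SD}S.$$

The six channels — $S$ birth, $S$ death, $S \to D$, $D$ birth, $D$ death,
$D \to S$ — are exactly the arrows of the standard interconversion diagram;
no asymmetric-division channels ($S \to S + D$) are included, as nothing in
the biology modelled here requires them and they are not separately
identifiable from marker-fraction data. The dedifferentiation rate $k_{DS}$
may be a piecewise-constant schedule in time: hypoxic exposure is modelled as
a step increase at a switch day (default day 3), the regime in which the
best description of hypoxic marker-conversion data is a dedifferentiation
rate roughly ten-fold higher after the switch than before it.

The marker-positive *fraction* $f = S/(S+D)$ obeys the autonomous Riccati
equation

$$\frac{df}{dt} = k_{DS}(1-f) - k_{SD}f + \Delta g\, f(1-f),
\qquad \Delta g = (\alpha_S-\delta_S) - (\alpha_D-\delta_D),$$

which depends only on the switching rates and the net-growth difference.
Two consequences shape the whole package: (i) fractions are invariant to the
absolute population size, so fits to FACS fractions cannot identify absolute
growth rates, only $\Delta g$; and (ii) from a pure marker-negative start
($S_0 = 0$, the experimental design of a sorted GD2(−) population) $f$ rises
monotonically to the stable root $f^*$ of
$\Delta g f^2 + (k_{SD}+k_{DS}-\Delta g)f - k_{DS} = 0$ —
`steady_state_fraction()` — a small but non-zero equilibrium for
biologically plausible rates.

The same six channels define a Markov jump process whose master equation we
never solve in production; `simulate_trajectory()` draws exact sample paths
(Gillespie-type SSA) and the test suite checks them against a
truncated-state-space matrix exponential.

## Parameters, units, defaults

All rates are per day and all times in days. The packaged scenarios
(`inst/extdata/scenarios.yaml`, loaded by `scenario()`) fix the synthetic
study conditions:

| parameter | normoxia | hypoxia | meaning |
|---|---|---|---|
| $\alpha_S,\ \delta_S$ | 0.8, 0.1 | 0.4, 0.1 | stem-like division / death |
| $\alpha_D,\ \delta_D$ | 0.9, 0.1 | 0.45, 0.1 | bulk division / death |
| $k_{SD}$ | 0.1 | 0.1 | differentiation |
| $k_{DS}$ | 0.002 | 0.002 → 0.02 at day 3 | dedifferentiation |

Only two features of this table are anchored in the modelled findings: the
day-3 switch with a ten-fold late/early ratio, and the qualitative ordering
(hypoxia suppresses growth; its stem-like equilibrium fraction exceeds the
normoxic one). Everything else is a fixture chosen once to be realistic:
division times around a day for transformed mammary epithelial lines,
"growth suppression" encoded as halved division rates with unchanged death
rates, and a normoxic equilibrium fraction of about 1% reached on a
multi-day timescale, versus roughly 12% in the late hypoxic regime.

```{r equilibria}
f_n <- steady_state_fraction(scenario("normoxia")$params)
late <- scenario("hypoxia")$params
late$k_DS <- cbind(start = 0, rate = 0.02)
c(normoxia = f_n, hypoxia_late = steady_state_fraction(late))
```

## The in-silico mammosphere assay

`simulate_mammosphere_rate()` reproduces the standard functional stemness
readout: each simulated well is seeded with a single biomarker-negative cell
(a sphere is a clonal outgrowth, and a per-run positivity call only makes
sense clonally), simulated stochastically for 10 days, and scored positive
when the total cell count *exceeds* 20 ("exceeds" read strictly: $S+D \ge
21$). The rate over the wells (default 100) is reported with an exact
Clopper–Pearson 95% interval, and `compare_conditions()` tests two arms with
the two-sided Fisher exact test under common random numbers.

A deliberate design choice separates the assay from the culture model. The
scenario's *culture* parameters describe adherent growth under each oxygen
tension and generate the marker time courses. The sphere assay, however, is
performed in a common non-adherent environment for both arms; what each arm
carries into it is the plasticity state acquired during exposure. The
scenarios therefore bundle separate *assay* parameters: shared growth rates
in which the stem-like compartment self-renews ($\alpha_S = 0.8$, $\delta_S
= 0.1$) while non-stem cells fail through anoikis ($\alpha_D = 0.3$,
$\delta_D = 0.35$, net negative), with the condition's acquired
dedifferentiation rate (0.002 normoxia, 0.02 hypoxia — the late-segment
value) carried over. Under this assay model sphere formation requires a
dedifferentiation event before the seeded clone dies out, so the rate is
strongly increasing in $k_{DS}$: hypoxia-exposed cells form spheres at a few
per cent, normoxic ones close to zero, matching both the direction and the
magnitude of wet-lab mammosphere efficiencies. Had the assay been simulated
under each condition's own culture parameters, halved hypoxic growth would
mechanically *reduce* hypoxic sphere counts — the opposite of what the assay
measures — which is why the assay environment is explicit rather than
implicit. Whether post-hypoxic spheres should instead retain hypoxic growth
rates remains configurable through `scenario(..., assay_params = )`.

## Grid-search estimation

`brute_force_search()` implements tolerance-band estimation exactly as an
exhaustive procedure: every point of a Cartesian grid is evaluated, *all*
points within the tolerance are accepted (no best-point selection), and each
parameter is summarised by the mean and SD over the accepted sets. The
headline statistic of `fit_two_phase_dedifferentiation()` is the ratio of
accepted-set means of the late and early dedifferentiation rates.

The loss is a Chebyshev (maximum) residual, the natural reading of a
per-solution tolerance band; three variants are available:

* `"max"` (default): largest absolute deviation between the model fraction
  (from `solve_deterministic()`, pure negative start) and the observed
  fraction, optionally combined by maximum with the absolute deviation of
  the in-silico mammosphere rate at a fixed seed (common random numbers
  across grid points keep the search deterministic and comparable).
* `"sse"`: sum of squared residuals, for users who prefer a quadratic loss.
* `"max_z"`: the maximum *standardised* residual, with each fraction
  residual mapped through the variance-stabilising arcsine square root,
  $z = 2\sqrt{n}\,|\!\sin^{-1}\!\sqrt{f_{obs}} - \sin^{-1}\!\sqrt{f_{mod}}|$,
  a standard-normal deviate under binomial FACS sampling whatever the
  fraction's magnitude.

The ratio-recovery analyses use `"max_z"` with tolerance 3.5 (standard-error
units). The reason is identifiability, not convenience: with a common
absolute band the tolerance must exceed the sampling noise of the
largest-variance timepoint (SE $\approx 0.003$ at $f \approx 0.07$,
$n = 10^4$), which then swamps the much smaller early-phase signal
($f(3) \approx 0.005$) and leaves the early rate — hence the ratio —
essentially unconstrained. On the error-scaled scale every timepoint is
equally informative; 3.5 SE makes a false rejection of the generating point
across nine timepoints a sub-1% event. The standardisation uses the
transform rather than an SE estimated from the observed fraction because the
estimated SE is biased low whenever a small count fluctuates low, which
spuriously inflates the standardised residual.

Dedifferentiation axes use a 1–2–5 logarithmic series spanning
$10^{-4}$–$1$ per day (`1e-4, 2e-4, 5e-4, …, 1`): it covers the plausible
range of daily switching rates at a step (at most 2.5×) fine enough to
resolve a ten-fold ratio, with 169 points for a two-axis search. Growth
rates enter the fits as per-condition constants: they are measured directly
by growth curves in this kind of study, and marker fractions cannot identify
them anyway (only $\Delta g$ enters the fraction dynamics).

```{r fit, eval = FALSE}
scn <- scenario("hypoxia")
axis <- c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 2e-2, 5e-2, 0.1, 0.2, 0.5, 1)
g <- grid_spec(alpha_S = scn$params$alpha_S, delta_S = scn$params$delta_S,
               alpha_D = scn$params$alpha_D, delta_D = scn$params$delta_D,
               k_SD = scn$params$k_SD, k_DS_early = axis, k_DS_late = axis)
fit <- fit_two_phase_dedifferentiation(g, generate_timecourse(scn),
                                       tolerance = 3.5, method = "max_z")
fit$kds_ratio   # ~10
```

## Signature overlap statistics

`derive_signature()` thresholds probe intensities against the reference
condition at two-fold, boundary inclusive in both directions ("two or more
times higher" ⇒ ratio ≥ 2; "two or more times lower" read as the reciprocal
fold, ratio ≤ 0.5, inclusive by symmetry). Signatures live on probes, not
collapsed genes, and the universe is always the full set of measured probes,
passed explicitly. `build_confusion()` partitions the universe into
overlap / exclusive / neither, and `fisher_exact_two_sided()` computes the
two-sided p-value by the point-probability (minimum-likelihood) convention —
the dominant two-sided convention for Fisher's exact test; doubling-based
alternatives exist and give different numbers. The implementation enumerates
the hypergeometric support on log weights with a relative tie tolerance of
$10^{-9}$; for tables with total at most 30 the integer weights are exactly
representable and the result matches exact enumeration to $10^{-12}$,
which the test suite verifies exhaustively. `overlap_report()` applies no
multiplicity adjustment, since none is applied in the analysis it mirrors.

## The synthetic-data generators

`generate_timecourse()` emulates a FACS marker-conversion experiment:
deterministic truth from a pure negative start, observed fractions as
binomial draws of $n = 10{,}000$ events per timepoint (typical cytometry
scale) on days 0–8. `generate_mammosphere_counts()` draws well counts
binomially at the assay's simulated rate. `generate_expression()` plants
fold-change probe sets (multiplied or divided by the fold before
multiplicative log-normal noise, default sdlog 0.1) with controlled pairwise
overlap via `plant_overlapping_sets()`.

What the generators do *not* emulate bounds what green tests can show:
no FACS gating error or autofluorescence (noise is purely binomial), no
day-to-day culture variability or replicate structure, no growth-curve
observations, no probe cross-hybridisation, batch or normalisation effects
in the expression matrices, and no modelling of sphere size in micrometres
(the 60-µm wet-lab cutoff maps to the 20-cell threshold only). Passing
recovery tests demonstrate the estimation machinery is sound under the
stated noise model, not that the model is identifiable under every real
data pathology.

## Numerical choices

* **ODE integration.** `lsoda` at rtol $10^{-10}$ / atol $10^{-12}$, with
  hard breakpoints at every $k_{DS}$ switch so the discontinuity is never
  smoothed. Each segment is integrated under a dominant-eigenvalue shift
  ($y = e^{c(t-a)}z$, $z' = (A - cI)z$): the integrated state stays $O(1)$,
  so neither strong growth nor strong decay erodes relative accuracy. The
  suite holds the solver to $10^{-8}$ norm-relative agreement with a
  segment-wise matrix exponential.
* **Undershoot clamp.** Integrator negatives smaller than $10^{-12}$ in
  magnitude are clamped to zero; anything larger is an error, not a clamp.
* **SSA.** Direct-method sampling via the integrated-hazard formulation: one
  Exp(1) variate per event, with unconsumed hazard carried across segment
  boundaries. This is exact for piecewise-constant propensities and makes a
  constant rate split into equal-rate segments reproduce the unsplit run
  draw for draw — a property the suite asserts. State recording on a fixed
  grid (default 0.1 day) by last-event carry-forward; (0,0) is absorbing;
  runs hitting the event cap are flagged, never silently dropped.
* **Seeding.** Every stochastic routine derives per-run seeds from a master
  seed by a fixed Lehmer step (`derive_seed()`), keeping all seeds below
  $2^{31}$; identical configuration implies identical output, which the
  pipeline manifest checks by checksum.
* **Degenerate inputs.** Extinct populations yield flagged `NA` fractions,
  not divisions by zero; empty accepted sets are an explicit failure state
  carrying the minimum loss; a zero mean early rate makes the ratio
  infinite with a warning; degenerate Fisher margins return $p = 1$; the
  sample odds ratio is `Inf`/`NaN`-flagged when off-diagonal cells vanish.

## Problem sizes

The shipped analyses and checks use: nine timepoints at $10^4$ FACS events;
100-run SSA ensembles (the assay's own protocol size) and 500-well assay
comparisons; two-axis 169-point or three-axis 507-point grids for the
dedifferentiation fits; 2000-run distributional checks against a
1,891-state truncated master equation; and exhaustive Fisher validation
over all 46,376 tables with total ≤ 30. These sizes were chosen so each
statistical check has comfortable power while the whole suite stays quick
on a laptop.

## Known limitations

Two compartments cannot represent a continuum of partial EMT states; oxygen
enters only through parameter values, with no dynamics of oxygen itself;
the brute-force fitter is exhaustive by design and scales multiplicatively
in axes (use pinned axes, not finer grids, when exploring); and the
two-sided exact test convention, while dominant, is one of several — p-values
near a decision boundary should not be compared across conventions.
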