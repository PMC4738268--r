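# cscplasticity

Tools for modelling cancer stem cell (CSC) plasticity under changing oxygen
conditions. Breast cancer populations contain a small stem-like subpopulation
(marked here by the ganglioside GD2) that interconverts with the non-stem
bulk; hypoxia increases that plasticity. This package implements the
computational side of such a study end to end, for modellers and
computational biologists who want the analysis reproducible from a single
seed:

* a **two-compartment interconversion model** — stem-like cells S and
  differentiated cells D with first-order division, death and switching:

      dS/dt = (alpha_S - delta_S) S - k_SD S + k_DS(t) D
      dD/dt = (alpha_D - delta_D) D - k_DS(t) D + k_SD S

  with a piecewise-constant dedifferentiation rate `k_DS(t)` (a step at
  day 3 encodes the hypoxia-induced plasticity switch), deterministic
  solutions, marker-fraction dynamics and the closed-form equilibrium
  fraction;
* an **exact stochastic simulator** (Gillespie-type SSA, Rcpp core) of the
  same six reaction channels, with reproducible seeded ensembles;
* an **in-silico mammosphere assay**: the fraction of clonal stochastic
  runs, seeded with one biomarker-negative cell, whose total cell count
  exceeds 20 after 10 days of simulated sphere culture — with exact binomial
  confidence intervals and a Fisher comparison between conditions;
* **brute-force grid estimation**: every parameter set on a fixed grid is
  evaluated, all sets within a tolerance band are accepted, and parameters
  are reported as mean ± SD over the accepted sets; the two-phase fit
  recovers the late/early dedifferentiation ratio;
* **gene-signature overlap statistics**: two-fold (boundary-inclusive)
  up/down probe signatures against a reference condition, 2×2 overlap
  confusion matrices, and a two-sided Fisher exact test implemented by
  enumeration (validated exhaustively against an exact oracle);
* **synthetic-data generators** for all of the above: GD2 fraction time
  courses with binomial FACS noise, mammosphere well counts, and expression
  matrices with planted fold-changes and controlled signature overlap.

## Worked example

Simulate a hypoxic marker-conversion experiment from a pure GD2(−) start and
recover the plasticity switch by grid search:

```r
library(cscplasticity)

scn <- scenario("hypoxia")          # packaged study conditions
tc  <- generate_timecourse(scn)     # binomial FACS noise, n = 10,000/day
tc$fractions
#>   time fraction     n
#> 1    0   0.0000 10000
#> 2    1   0.0014 10000
#> 3    2   0.0037 10000
#> 4    3   0.0051 10000
#> 5    4   0.0252 10000
#> 6    5   0.0370 10000
#> 7    6   0.0480 10000
#> 8    7   0.0629 10000
#> 9    8   0.0727 10000
```

The fraction creeps towards about half a per cent in the first three days,
then accelerates — the day-3 switch. Fit early and late dedifferentiation
rates jointly on a 1–2–5 logarithmic grid:

```r
axis <- c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 2e-2, 5e-2, 0.1, 0.2, 0.5, 1)
g <- grid_spec(alpha_S = scn$params$alpha_S, delta_S = scn$params$delta_S,
               alpha_D = scn$params$alpha_D, delta_D = scn$params$delta_D,
               k_SD = scn$params$k_SD, k_DS_early = axis, k_DS_late = axis)
fit <- fit_two_phase_dedifferentiation(g, tc, switch_day = 3,
                                       tolerance = 3.5, method = "max_z")
fit
#> Brute-force grid fit: 1 of 169 grid points within tolerance 3.5
#>   alpha_S    mean 0.4  sd 0
#>   delta_S    mean 0.1  sd 0
#>   alpha_D    mean 0.45  sd 0
#>   delta_D    mean 0.1  sd 0
#>   k_SD       mean 0.1  sd 0
#>   k_DS_early mean 0.002  sd 0
#>   k_DS_late  mean 0.02  sd 0
#>   late/early dedifferentiation ratio: 10
```

The accepted sets put the dedifferentiation rate about ten-fold higher after
day 3 than before it. The mammosphere side of the story:

```r
cmp <- compare_conditions(scenario("normoxia")$assay_params,
                          scn$assay_params,
                          mammosphere_protocol(n_runs = 500, seed = 29))
c(normoxia = cmp$normoxia$rate, hypoxia = cmp$hypoxia$rate, p = cmp$p_value)
#>     normoxia      hypoxia            p
#> 0.000000e+00 5.200000e-02 2.134983e-08
```

Hypoxia-exposed cells, carrying the higher dedifferentiation rate into a
common sphere-culture environment, form spheres at ~5% versus ~0% —
significantly more often by the two-sided Fisher exact test.

The numbered scripts under `analysis/` run the full story —
`01_simulate_scenarios.R`, `02_mammosphere_assay.R`,
`03_fit_dedifferentiation.R`, `04_signature_overlap.R` — each a thin driver
over the package that prints its finding and writes tables under
`results/`. `run_pipeline()` orchestrates the same stages from a single
config with a checksummed artifact manifest. The methods vignette
(`vignettes/csc-plasticity-model.Rmd`) documents the model, the loss and
grid choices, the assay parameterisation and the numerical decisions.

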