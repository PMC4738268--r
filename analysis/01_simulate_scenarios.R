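#!/usr/bin/env Rscript
# Deterministic and stochastic dynamics of the two oxygen regimes.
#
# Starting from a pure biomarker-negative (GD2-) culture, the positive
# fraction rises towards a small non-zero equilibrium. Under normoxia the
# rise is slow and still incomplete after 8 days; under hypoxia the
# dedifferentiation rate switches ten-fold upwards at day 3 and the fraction
# accelerates between days 3 and 6. SSA ensembles (100 runs) bracket the
# mean-field curves.

library(cscplasticity)

dir.create("results", showWarnings = FALSE)

for (nm in c("normoxia", "hypoxia")) {
  scn <- scenario(nm)
  times <- seq(0, 8, by = 0.1)
  traj <- solve_deterministic(population_state(0, S = 0, D = 1000),
                              scn$params, times)
  write_trajectory(traj, sprintf("results/trajectory_%s.csv", nm))

  ens <- simulate_ensemble(population_state(0, S = 0, D = 100), scn$params,
                           ssa_config(t_end = 8, seed = scn$seed), 100)
  write_ensemble(ens, sprintf("results/ensemble_%s.csv", nm),
                 sprintf("results/ensemble_finals_%s.csv", nm))

  f <- fraction_positive(traj)
  cat(sprintf("%s: f(3) = %.4f, f(6) = %.4f, f(8) = %.4f\n",
              nm, f[times == 3], f[times == 6], f[times == 8]))
}

f_norm <- steady_state_fraction(scenario("normoxia")$params)
hyp <- scenario("hypoxia")$params
hyp$k_DS <- cbind(start = 0, rate = unname(hyp$k_DS[2, "rate"]))
f_hyp <- steady_state_fraction(hyp)
cat(sprintf("equilibrium positive fraction: normoxia %.4f, hypoxia (late) %.4f\n",
            f_norm, f_hyp))
stopifnot(f_hyp > f_norm)
cat("finding: the hypoxic regime supports a larger stem-like equilibrium.\n")
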