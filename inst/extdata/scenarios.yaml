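# Packaged synthetic-data scenarios (all rates per day, times in days).
#
# `params` are the culture dynamics generating the biomarker-fraction time
# courses (pure biomarker-negative start):
#   normoxia: slow spontaneous dedifferentiation; the positive fraction rises
#     from zero towards a small non-zero equilibrium over more than 8 days.
#   hypoxia: division rates halved (growth suppression under 1% O2) and a
#     two-segment dedifferentiation schedule switching at day 3 with a
#     ten-fold late/early ratio (the plasticity switch regime).
#
# `assay` are the sphere-culture dynamics used by the in-silico mammosphere
# protocol: both arms are assayed in the same non-adherent environment, where
# stem-like cells self-renew (net positive growth) and non-stem cells fail
# (anoikis, net negative growth); each arm carries over the dedifferentiation
# rate acquired under its exposure (the late-segment value for hypoxia).
normoxia:
  params:
    alpha_S: 0.8
    delta_S: 0.1
    alpha_D: 0.9
    delta_D: 0.1
    k_SD: 0.1
    k_DS: 0.002
  assay:
    alpha_S: 0.8
    delta_S: 0.1
    alpha_D: 0.3
    delta_D: 0.35
    k_SD: 0.1
    k_DS: 0.002
  facs_n: 10000
  days: [0, 1, 2, 3, 4, 5, 6, 7, 8]
  mammosphere:
    init_cells: 1
    end_time: 10
    threshold: 20
    n_runs: 100
  seed: 20101
hypoxia:
  params:
    alpha_S: 0.4
    delta_S: 0.1
    alpha_D: 0.45
    delta_D: 0.1
    k_SD: 0.1
    k_DS:
      - [0.0, 0.002]
      - [3.0, 0.02]
  assay:
    alpha_S: 0.8
    delta_S: 0.1
    alpha_D: 0.3
    delta_D: 0.35
    k_SD: 0.1
    k_DS: 0.02
  facs_n: 10000
  days: [0, 1, 2, 3, 4, 5, 6, 7, 8]
  mammosphere:
    init_cells: 1
    end_time: 10
    threshold: 20
    n_runs: 100
  seed: 20102
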