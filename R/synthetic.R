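#' Named synthetic-data scenarios
#'
#' A scenario bundles everything needed to generate the study's inputs: the
#' culture-model parameters generating the biomarker-fraction time course
#' (pure biomarker-negative start), the sphere-culture parameters used by the
#' in-silico mammosphere assay, the FACS sample size per timepoint, the
#' observation days and the master seed. The packaged `"normoxia"` and
#' `"hypoxia"` scenarios are read from the scenario config shipped with the
#' package (`inst/extdata/scenarios.yaml`); the hypoxia scenario carries a
#' two-segment dedifferentiation schedule switching at day 3 with a ten-fold
#' late/early ratio.
#'
#' The assay parameters differ from the culture parameters on purpose: sphere
#' culture is a common non-adherent environment for both arms, in which
#' stem-like cells self-renew while non-stem cells fail (anoikis); each arm
#' carries over only the dedifferentiation rate acquired under its exposure.
#'
#' @param name `"normoxia"`, `"hypoxia"`, or `"custom"`.
#' @param params culture [model_parameters()] (required for `"custom"`).
#' @param assay_params assay [model_parameters()]; defaults to `params`.
#' @param facs_n FACS events per timepoint (default 10000).
#' @param days observation days (default 0:8).
#' @param proto a [mammosphere_protocol()].
#' @param seed master seed.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = c("normoxia", "hypoxia", "custom"),
                     params = NULL, assay_params = NULL, facs_n = 10000L,
                     days = 0:8, proto = mammosphere_protocol(), seed = 1L) {
  name <- match.arg(name)
  if (name != "custom") {
    cfg <- load_scenario_config()[[name]]
    params <- params_from_config(cfg$params)
    assay_params <- params_from_config(cfg$assay)
    facs_n <- as.integer(cfg$facs_n)
    days <- as.numeric(cfg$days)
    proto <- do.call(mammosphere_protocol,
                     c(cfg$mammosphere, list(seed = cfg$seed)))
    seed <- as.integer(cfg$seed)
  } else {
    if (is.null(params)) stop("custom scenario requires params")
    if (is.null(assay_params)) assay_params <- params
  }
  stopifnot(inherits(params, "model_parameters"),
            inherits(assay_params, "model_parameters"))
  structure(list(name = name, params = params, assay_params = assay_params,
                 facs_n = as.integer(facs_n), days = sort(unique(days)),
                 proto = proto, seed = as.integer(seed)),
            class = "scenario")
}

load_scenario_config <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "cscplasticity")
  if (!nzchar(path)) stop("packaged scenario config not found")
  yaml::read_yaml(path)
}

# model_parameters from a config block (k_DS scalar or list of [start, rate])
params_from_config <- function(p) {
  kds <- p$k_DS
  if (is.list(kds)) {
    kds <- do.call(rbind, lapply(kds, as.numeric))
    colnames(kds) <- c("start", "rate")
  }
  model_parameters(alpha_S = p$alpha_S, delta_S = p$delta_S,
                   alpha_D = p$alpha_D, delta_D = p$delta_D,
                   k_SD = p$k_SD, k_DS = kds)
}

#' Generate a biomarker-fraction time course with FACS sampling noise
#'
#' The true fraction comes from [solve_deterministic()] starting from a pure
#' biomarker-negative population (S = 0); the observed fraction at each
#' observation day is a binomial draw of `facs_n` events at the true
#' fraction, divided by `facs_n`. With `noise = FALSE` the true fractions are
#' returned (the infinite-sample limit).
#'
#' @param scn a [scenario()].
#' @param noise logical; apply binomial FACS sampling noise (default TRUE).
#' @return A [fit_data()] whose `fractions` have columns `time`, `fraction`,
#'   `n`, with the noiseless fractions in attribute `true_fraction`.
#' @export
generate_timecourse <- function(scn, noise = TRUE) {
  stopifnot(inherits(scn, "scenario"))
  times <- scn$days
  if (times[1] != 0) times <- c(0, times)
  traj <- solve_deterministic(population_state(0, S = 0, D = 1),
                              scn$params, times)
  f_true <- fraction_positive(traj)[match(scn$days, traj$t)]
  if (noise) {
    set.seed(derive_seed(scn$seed, 101L))
    f_obs <- stats::rbinom(length(f_true), scn$facs_n, f_true) / scn$facs_n
  } else {
    f_obs <- f_true
  }
  out <- fit_data(data.frame(time = scn$days, fraction = f_obs,
                             n = scn$facs_n))
  attr(out, "true_fraction") <- f_true
  out
}

#' Generate mammosphere assay counts for a scenario
#'
#' The sphere-formation probability is the in-silico mammosphere rate under
#' the scenario's assay parameters; the observed count of positive wells is a
#' binomial draw at that rate.
#'
#' @param scn a [scenario()].
#' @param wells number of wells seeded (>= 1).
#' @return named integer vector `c(positives = , wells = )`, with the
#'   generating rate in attribute `rate`.
#' @export
generate_mammosphere_counts <- function(scn, wells) {
  stopifnot(inherits(scn, "scenario"), wells >= 1)
  res <- simulate_mammosphere_rate(scn$assay_params, scn$proto)
  set.seed(derive_seed(scn$seed, 202L))
  pos <- stats::rbinom(1, wells, res$rate)
  out <- c(positives = pos, wells = as.integer(wells))
  attr(out, "rate") <- res$rate
  out
}

#' Specification of a synthetic expression matrix
#'
#' Plants fold-change signatures into a probe universe: each condition gets
#' disjoint up and down probe sets, multiplied (divided) by its fold factor
#' before multiplicative log-normal noise. Pairwise signature overlap between
#' two conditions is controlled by the fraction of planted probes they share.
#'
#' @param n_probes probe universe size.
#' @param conditions named list; each element a list with `up` and `down`
#'   integer probe indices (disjoint within the condition) and `fold`
#'   (>= 2).
#' @param noise_sdlog log-normal noise dispersion (sdlog; 0 disables noise).
#' @param baseline baseline intensity of unperturbed probes.
#' @param seed random seed.
#' @return A `synthetic_expression_spec` object.
#' @export
synthetic_expression_spec <- function(n_probes, conditions,
                                      noise_sdlog = 0.1, baseline = 100,
                                      seed = 1L) {
  stopifnot(n_probes >= 1, length(conditions) >= 1)
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    up <- cond$up %||% integer(0)
    dn <- cond$down %||% integer(0)
    if (length(intersect(up, dn))) {
      stop("planted up and down sets must be disjoint within a condition")
    }
    if (length(up) && max(up) > n_probes || length(dn) && max(dn) > n_probes) {
      stop("planted sets exceed the probe universe")
    }
    if (!is.null(cond$fold) && cond$fold < 2) stop("fold must be >= 2")
  }
  structure(list(n_probes = as.integer(n_probes), conditions = conditions,
                 noise_sdlog = noise_sdlog, baseline = baseline,
                 seed = as.integer(seed)),
            class = "synthetic_expression_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant two probe sets with a controlled overlap fraction
#'
#' Utility for building paired-signature scenarios: draws two probe index
#' sets of the given size from the universe sharing `overlap_frac` of their
#' members.
#'
#' @param n_probes universe size.
#' @param size size of each set.
#' @param overlap_frac fraction of shared probes in `[0, 1]`.
#' @param seed random seed.
#' @return list with integer index vectors `A` and `B`.
#' @export
plant_overlapping_sets <- function(n_probes, size, overlap_frac, seed = 1L) {
  stopifnot(overlap_frac >= 0, overlap_frac <= 1)
  n_shared <- round(size * overlap_frac)
  need <- 2 * size - n_shared
  if (need > n_probes) stop("sets do not fit in the universe")
  set.seed(seed)
  idx <- sample.int(n_probes, need)
  shared <- if (n_shared > 0) idx[seq_len(n_shared)] else integer(0)
  rest <- if (n_shared > 0) idx[-seq_len(n_shared)] else idx
  k <- size - n_shared
  list(A = sort(c(shared, rest[seq_len(k)])),
       B = sort(c(shared, if (k > 0) rest[(k + 1):(2 * k)] else integer(0))))
}

#' Generate a synthetic expression table with planted signatures
#'
#' Reference intensities are log-normal around the baseline; planted up
#' probes of each condition are multiplied by the condition's fold factor
#' before noise, planted down probes divided by it.
#'
#' @param spec a [synthetic_expression_spec()].
#' @return An [expression_table()] with a `ref` reference column and one
#'   column per condition.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_expression_spec"))
  set.seed(spec$seed)
  n <- spec$n_probes
  lnoise <- function() {
    if (spec$noise_sdlog > 0) stats::rlnorm(n, 0, spec$noise_sdlog) else rep(1, n)
  }
  df <- data.frame(probe = sprintf("p%05d", seq_len(n)))
  df$ref <- spec$baseline * lnoise()
  for (nm in names(spec$conditions)) {
    cond <- spec$conditions[[nm]]
    fold <- cond$fold %||% 4
    mu <- rep(spec$baseline, n)
    mu[cond$up %||% integer(0)] <- spec$baseline * fold
    mu[cond$down %||% integer(0)] <- spec$baseline / fold
    df[[nm]] <- mu * lnoise()
  }
  expression_table(df, reference = "ref")
}
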