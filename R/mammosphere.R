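#' In-silico mammosphere assay protocol
#'
#' A mammosphere is a clonal sphere grown from a single cell under
#' non-adherent conditions; sphere formation is the standard functional
#' readout of stem-like self-renewal. The in-silico counterpart seeds each
#' simulated "well" with biomarker-negative cells and calls a run positive
#' when the total cell count at the end of the culture period exceeds the
#' threshold ("exceeded" read strictly: positivity requires S + D >
#' `threshold`).
#'
#' @param init_cells number of biomarker-negative cells seeded per run
#'   (default 1: a sphere is a clonal outgrowth).
#' @param end_time culture period in days (default 10).
#' @param threshold positivity threshold on the total cell count (default 20).
#' @param n_runs number of simulated wells (default 100).
#' @param seed master seed; per-run seeds are derived from it.
#' @param max_events per-run reaction-event cap. A run that hits the cap is
#'   scored on its state at truncation and counted in `truncated`; for
#'   growing clones far beyond the threshold this leaves the positivity call
#'   unchanged while bounding the cost of explosive parameter sets.
#' @return An object of class `mammosphere_protocol`.
#' @export
mammosphere_protocol <- function(init_cells = 1L, end_time = 10, threshold = 20L,
                                 n_runs = 100L, seed = 1L, max_events = 1e6) {
  if (threshold < 1) stop("threshold must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (end_time <= 0) stop("end_time must be positive")
  if (init_cells < 1) stop("init_cells must be >= 1")
  if (max_events < 1) stop("max_events must be positive")
  structure(list(init_cells = as.integer(init_cells), end_time = end_time,
                 threshold = as.integer(threshold), n_runs = as.integer(n_runs),
                 seed = as.integer(seed), max_events = max_events),
            class = "mammosphere_protocol")
}

#' Simulate the in-silico mammosphere formation rate
#'
#' Runs `proto$n_runs` independent clonal SSA runs from `proto$init_cells`
#' biomarker-negative cells and reports the fraction of runs whose total cell
#' count at `proto$end_time` exceeds `proto$threshold`, with an exact
#' Clopper-Pearson 95% binomial confidence interval.
#'
#' @param params a [model_parameters()] object.
#' @param proto a [mammosphere_protocol()].
#' @return A `mammosphere_result` list: `rate`, `ci` (length-2 vector),
#'   `positives`, `n_runs`, `finals` (data.frame `run`, `seed`, `S_final`,
#'   `D_final`, `positive`), `protocol`.
#' @export
simulate_mammosphere_rate <- function(params, proto) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(proto, "mammosphere_protocol"))
  n <- proto$n_runs
  seeds <- vapply(seq_len(n), function(r) derive_seed(proto$seed, r),
                  integer(1))
  Sf <- integer(n)
  Df <- integer(n)
  trunc_n <- 0L
  grid <- c(0, proto$end_time)
  for (r in seq_len(n)) {
    set.seed(seeds[r])
    res <- .ssa_run(0L, proto$init_cells, 0, proto$end_time,
                    params$alpha_S, params$delta_S, params$alpha_D,
                    params$delta_D, params$k_SD,
                    params$k_DS[, "start"], params$k_DS[, "rate"],
                    grid, proto$max_events)
    Sf[r] <- res$S_final
    Df[r] <- res$D_final
    if (res$truncated) trunc_n <- trunc_n + 1L
  }
  positive <- (Sf + Df) > proto$threshold
  k <- sum(positive)
  ci <- as.numeric(stats::binom.test(k, n)$conf.int)
  structure(list(rate = k / n, ci = ci, positives = k, n_runs = n,
                 truncated = trunc_n,
                 finals = data.frame(run = seq_len(n), seed = seeds,
                                     S_final = Sf, D_final = Df,
                                     positive = positive),
                 protocol = proto),
            class = "mammosphere_result")
}

#' Compare mammosphere formation between two conditions
#'
#' Simulates the in-silico mammosphere rate under both parameter sets with
#' the same protocol (identical per-run seeds, i.e. common random numbers)
#' and tests the difference with a two-sided Fisher exact test on the 2x2
#' positives/negatives table.
#'
#' @param params_normoxia,params_hypoxia [model_parameters()] for the two
#'   conditions.
#' @param proto a [mammosphere_protocol()] shared by both arms.
#' @return list with `normoxia` and `hypoxia` (`mammosphere_result`s),
#'   `p_value`, `odds_ratio`, and the 2x2 `table`
#'   (rows = condition, cols = positive/negative).
#' @export
compare_conditions <- function(params_normoxia, params_hypoxia, proto) {
  rn <- simulate_mammosphere_rate(params_normoxia, proto)
  rh <- simulate_mammosphere_rate(params_hypoxia, proto)
  tab <- matrix(c(rn$positives, rn$n_runs - rn$positives,
                  rh$positives, rh$n_runs - rh$positives),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("normoxia", "hypoxia"),
                                c("positive", "negative")))
  ft <- fisher_exact_two_sided(tab)
  list(normoxia = rn, hypoxia = rh, p_value = ft$p_value,
       odds_ratio = ft$odds_ratio, table = tab)
}
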