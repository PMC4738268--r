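#' Configuration for a stochastic simulation run
#'
#' @param t_end end time in days (> 0).
#' @param seed integer random seed.
#' @param max_events maximum number of reaction events before a run is flagged
#'   truncated (guards against runaway growth).
#' @param grid_dt spacing of the state-recording grid in days; states are
#'   recorded by last-event carry-forward. Ignored when `grid` is supplied.
#' @param grid optional explicit strictly increasing recording grid starting at
#'   the initial time.
#' @return An object of class `ssa_config`.
#' @export
ssa_config <- function(t_end, seed = 1L, max_events = 1e7, grid_dt = 0.1,
                       grid = NULL) {
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (max_events <= 0) stop("max_events must be positive")
  if (!is.null(grid) && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing")
  }
  structure(list(t_end = t_end, seed = as.integer(seed),
                 max_events = max_events, grid_dt = grid_dt, grid = grid),
            class = "ssa_config")
}

#' Propensities of the six reaction channels
#'
#' Channel order: S birth, S death, S->D, D birth, D death, D->S. Each
#' propensity is the channel rate times the count of its source compartment,
#' so no channel can fire from an empty compartment.
#'
#' @param state a [population_state()] with integer counts.
#' @param params a [model_parameters()] object.
#' @param t time at which to evaluate the (possibly piecewise) `k_DS`.
#' @return named numeric vector of six non-negative propensities (events/day).
#' @export
propensities <- function(state, params, t = state$t) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "model_parameters"))
  if (state$S < 0 || state$D < 0) stop("counts must be non-negative")
  kds <- kds_at(params, t)
  c(S_birth = params$alpha_S * state$S,
    S_death = params$delta_S * state$S,
    S_to_D  = params$k_SD * state$S,
    D_birth = params$alpha_D * state$D,
    D_death = params$delta_D * state$D,
    D_to_S  = kds * state$D)
}

ssa_grid <- function(init_t, cfg) {
  if (!is.null(cfg$grid)) {
    if (abs(cfg$grid[1] - init_t) > 1e-12) {
      stop("recording grid must start at the initial time")
    }
    return(cfg$grid)
  }
  unique(c(seq(init_t, cfg$t_end, by = cfg$grid_dt), cfg$t_end))
}

#' Simulate one exact SSA sample path
#'
#' Exact Gillespie-type simulation of the six-channel network. With a
#' piecewise `k_DS`, event times come from the integrated-hazard formulation
#' (one Exp(1) variate per event, the unconsumed hazard carried across
#' segment boundaries), so no reaction ever fires with a rate from the wrong
#' segment and a constant rate split into equal-rate segments reproduces the
#' unsplit sample path draw for draw. The state (0, 0) is absorbing.
#'
#' @param init a [population_state()] with integer counts.
#' @param params a [model_parameters()] object.
#' @param cfg an [ssa_config()].
#' @return A `trajectory` data.frame (`t`, `S`, `D`) of integer states on the
#'   recording grid, with attributes `final` (named final state), `n_events`,
#'   `truncated` (TRUE if the run hit `max_events`) and `seed`.
#' @export
simulate_trajectory <- function(init, params, cfg) {
  stopifnot(inherits(init, "population_state"),
            inherits(params, "model_parameters"),
            inherits(cfg, "ssa_config"))
  if (init$S != round(init$S) || init$D != round(init$D)) {
    stop("stochastic simulation requires integer initial counts")
  }
  grid <- ssa_grid(init$t, cfg)
  set.seed(cfg$seed)
  res <- .ssa_run(as.integer(init$S), as.integer(init$D), init$t, cfg$t_end,
                  params$alpha_S, params$delta_S, params$alpha_D,
                  params$delta_D, params$k_SD,
                  params$k_DS[, "start"], params$k_DS[, "rate"],
                  grid, cfg$max_events)
  if (res$truncated) {
    warning("SSA run truncated at max_events; trajectory is incomplete")
  }
  traj <- data.frame(t = grid, S = res$S, D = res$D)
  attr(traj, "final") <- c(S = res$S_final, D = res$D_final)
  attr(traj, "n_events") <- res$n_events
  attr(traj, "truncated") <- res$truncated
  attr(traj, "seed") <- cfg$seed
  class(traj) <- c("trajectory", "data.frame")
  traj
}

# deterministic per-run seed from a master seed (Lehmer step, kept < 2^31)
derive_seed <- function(master_seed, run) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 +
                as.numeric(run) * 16807) %% 2147483629 + 1)
}

#' Simulate an ensemble of SSA runs
#'
#' Runs `n_runs` independent sample paths with per-run seeds derived
#' deterministically from the master seed in `cfg`, and summarises the
#' ensemble on the recording grid. The mean fraction at each grid time is
#' taken over runs that are not extinct there.
#'
#' @inheritParams simulate_trajectory
#' @param n_runs number of runs (>= 1).
#' @return An `ensemble_result` list: `summary` (data.frame `t`, `mean_S`,
#'   `mean_D`, `mean_f`, `var_S`, `var_D`), `finals` (data.frame `run`,
#'   `seed`, `S_final`, `D_final`), `n_runs`, `master_seed`.
#' @export
simulate_ensemble <- function(init, params, cfg, n_runs) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  grid <- ssa_grid(init$t, cfg)
  ng <- length(grid)
  Smat <- matrix(0L, nrow = ng, ncol = n_runs)
  Dmat <- matrix(0L, nrow = ng, ncol = n_runs)
  seeds <- vapply(seq_len(n_runs), function(r) derive_seed(cfg$seed, r),
                  integer(1))
  finals <- data.frame(run = seq_len(n_runs), seed = seeds,
                       S_final = 0L, D_final = 0L)
  for (r in seq_len(n_runs)) {
    run_cfg <- cfg
    run_cfg$seed <- seeds[r]
    run_cfg$grid <- grid
    traj <- simulate_trajectory(init, params, run_cfg)
    Smat[, r] <- traj$S
    Dmat[, r] <- traj$D
    fin <- attr(traj, "final")
    finals$S_final[r] <- fin[["S"]]
    finals$D_final[r] <- fin[["D"]]
  }
  tot <- Smat + Dmat
  fmat <- ifelse(tot > 0, Smat / tot, NA_real_)
  summary <- data.frame(
    t = grid,
    mean_S = rowMeans(Smat),
    mean_D = rowMeans(Dmat),
    mean_f = rowMeans(fmat, na.rm = TRUE),
    var_S = apply(Smat, 1, stats::var),
    var_D = apply(Dmat, 1, stats::var)
  )
  structure(list(summary = summary, finals = finals, n_runs = n_runs,
                 master_seed = cfg$seed),
            class = "ensemble_result")
}

#' Write ensemble summaries as delimited text
#'
#' Writes the grid summary as `t,mean_S,mean_D,mean_f,var_S,var_D` and,
#' optionally, the per-run final states as `run,seed,S_final,D_final`.
#'
#' @param ens an `ensemble_result` from [simulate_ensemble()].
#' @param path CSV path for the summary table.
#' @param finals_path optional CSV path for the per-run final states.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, finals_path = NULL) {
  utils::write.csv(ens$summary, path, row.names = FALSE, quote = FALSE)
  if (!is.null(finals_path)) {
    utils::write.csv(ens$finals, finals_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
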