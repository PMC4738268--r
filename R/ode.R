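#' Right-hand side of the deterministic two-compartment model
#'
#' The mean-field dynamics of the six first-order reaction channels:
#' \deqn{dS/dt = (\alpha_S - \delta_S) S - k_{SD} S + k_{DS}(t) D}
#' \deqn{dD/dt = (\alpha_D - \delta_D) D - k_{DS}(t) D + k_{SD} S}
#'
#' @param state a [population_state()] (its `t` selects the active `k_DS`
#'   segment).
#' @param params a [model_parameters()] object.
#' @return named numeric vector `c(dS, dD)` of time derivatives (cells/day).
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "model_parameters"))
  kds <- kds_at(params, state$t)
  dS <- (params$alpha_S - params$delta_S) * state$S -
    params$k_SD * state$S + kds * state$D
  dD <- (params$alpha_D - params$delta_D) * state$D -
    kds * state$D + params$k_SD * state$S
  c(dS = dS, dD = dD)
}

# 2x2 rate matrix of the linear system for a fixed k_DS value,
# acting on the column vector (S, D)
rate_matrix <- function(params, kds) {
  matrix(c(params$alpha_S - params$delta_S - params$k_SD, params$k_SD,
           kds, params$alpha_D - params$delta_D - kds),
         nrow = 2, byrow = FALSE,
         dimnames = list(c("S", "D"), c("S", "D")))
}

#' Solve the deterministic model on a time grid
#'
#' Integrates the (piecewise-)linear system with `deSolve::lsoda` at relative
#' tolerance 1e-10, forcing integration breakpoints at every `k_DS` segment
#' switch so the discontinuous rate is never smoothed across a boundary.
#' Negative undershoot from the integrator smaller than 1e-12 in magnitude is
#' clamped to zero; anything larger raises an error.
#'
#' @param init a [population_state()]; integration starts at `init$t`.
#' @param params a [model_parameters()] object.
#' @param output_times strictly increasing times (days) starting at `init$t`.
#' @return A `trajectory`: data.frame with columns `t`, `S`, `D` and attributes
#'   `params` (the parameters used) and `solver` (settings).
#' @export
solve_deterministic <- function(init, params, output_times) {
  stopifnot(inherits(init, "population_state"),
            inherits(params, "model_parameters"))
  output_times <- as.numeric(output_times)
  if (length(output_times) < 1L || any(diff(output_times) <= 0)) {
    stop("output_times must be strictly increasing")
  }
  if (abs(output_times[1] - init$t) > 1e-12) {
    stop("output_times must start at the initial time")
  }
  t0 <- init$t
  t_end <- output_times[length(output_times)]
  breaks <- params$k_DS[, "start"]
  breaks <- breaks[breaks > t0 & breaks < t_end]
  seg_edges <- unique(c(t0, breaks, t_end))

  rtol <- 1e-10
  atol <- 1e-12
  out <- matrix(NA_real_, nrow = length(output_times), ncol = 2,
                dimnames = list(NULL, c("S", "D")))
  out[1, ] <- c(init$S, init$D)
  y <- c(S = init$S, D = init$D)
  for (i in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[i]
    b <- seg_edges[i + 1L]
    kds <- kds_at(params, a)
    A <- rate_matrix(params, kds)
    # dominant-eigenvalue shift: integrate y = exp(c (t - a)) z with
    # z' = (A - c I) z, so the integrated state stays O(1) and neither
    # exponential growth nor decay erodes the achievable relative accuracy
    trA <- A[1, 1] + A[2, 2]
    detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    disc <- trA^2 - 4 * detA
    cs <- if (disc >= 0) (trA + sqrt(disc)) / 2 else trA / 2
    As <- A - diag(cs, 2)
    deriv <- function(t, y, parms) list(as.vector(As %*% y))
    keep <- which(output_times > a & output_times <= b)
    times <- unique(c(a, output_times[keep], b))
    if (length(times) < 2L) times <- c(a, b)
    sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    scale <- exp(cs * (sol[, "time"] - a))
    if (length(keep)) {
      idx <- match(output_times[keep], sol[, "time"])
      out[keep, ] <- sol[idx, c("S", "D"), drop = FALSE] * scale[idx]
    }
    y <- sol[nrow(sol), c("S", "D")] * scale[length(scale)]
  }
  if (any(!is.finite(out))) stop("deterministic solution overflowed")
  neg <- out < 0
  if (any(out[neg] < -1e-12)) {
    stop("integrator produced a negative population beyond clamping tolerance")
  }
  out[neg] <- 0
  traj <- data.frame(t = output_times, S = out[, "S"], D = out[, "D"])
  attr(traj, "params") <- params
  attr(traj, "solver") <- list(method = "lsoda", rtol = rtol, atol = atol)
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Biomarker-positive fraction along a trajectory
#'
#' Computes f = S / (S + D) at each trajectory time. Times at which the
#' population is extinct (S + D = 0) are flagged with `NA` and a warning
#' rather than a silent division by zero.
#'
#' @param traj a trajectory data.frame with columns `t`, `S`, `D`.
#' @return numeric vector of fractions in `[0, 1]` (or `NA` where extinct),
#'   one per trajectory row.
#' @export
fraction_positive <- function(traj) {
  stopifnot(all(c("t", "S", "D") %in% names(traj)))
  tot <- traj$S + traj$D
  f <- ifelse(tot > 0, traj$S / tot, NA_real_)
  if (anyNA(f)) warning("extinct population at some times; fraction flagged NA")
  f
}

#' Equilibrium biomarker-positive fraction
#'
#' For a constant dedifferentiation rate the fraction f = S/(S+D) obeys the
#' autonomous Riccati equation
#' df/dt = k_DS (1 - f) - k_SD f + dg f (1 - f), with
#' dg = (alpha_S - delta_S) - (alpha_D - delta_D) the net-growth advantage of
#' the stem-like compartment. The stable equilibrium is the root in `[0, 1]` of
#' dg f^2 + (k_SD + k_DS - dg) f - k_DS = 0 (linear case when dg = 0). A pure
#' biomarker-negative culture relaxes to this value, the small non-zero
#' equilibrium fraction seen in marker-conversion time courses.
#'
#' @param params a [model_parameters()] with a single (constant) `k_DS`
#'   segment; piecewise schedules are rejected.
#' @return equilibrium fraction in `[0, 1]`.
#' @export
steady_state_fraction <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  if (!kds_is_constant(params)) {
    stop("steady_state_fraction requires a constant k_DS; pass a single segment")
  }
  kds <- unname(params$k_DS[1, "rate"])
  ksd <- params$k_SD
  dg <- (params$alpha_S - params$delta_S) - (params$alpha_D - params$delta_D)
  if (dg == 0) {
    if (ksd + kds == 0) stop("degenerate: k_SD + k_DS = 0 with equal net growth")
    return(kds / (ksd + kds))
  }
  # dg f^2 + (ksd + kds - dg) f - kds = 0
  b <- ksd + kds - dg
  disc <- b^2 + 4 * dg * kds
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * dg)
  f <- roots[roots >= -1e-12 & roots <= 1 + 1e-12]
  if (!length(f)) stop("no equilibrium fraction in [0, 1]")
  # the root in [0,1] with negative derivative of the Riccati RHS is stable;
  # for this system at most one root lies in [0,1] apart from ties
  min(max(f[1], 0), 1)
}

#' Write / read a trajectory as delimited text
#'
#' The on-disk format is CSV with header `t,S,D,f`, where `f` is the
#' biomarker-positive fraction (empty where the population is extinct).
#'
#' @param traj trajectory data.frame with columns `t`, `S`, `D`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory data.frame (with `f` recomputed from `S`, `D`).
#' @export
write_trajectory <- function(traj, path) {
  f <- suppressWarnings(fraction_positive(traj))
  utils::write.csv(data.frame(t = traj$t, S = traj$S, D = traj$D, f = f),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "S", "D") %in% names(df)))
  df$f <- ifelse(df$S + df$D > 0, df$S / (df$S + df$D), NA_real_)
  class(df) <- c("trajectory", "data.frame")
  df
}
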