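#' Grid specification for brute-force parameter search
#'
#' The search space is the Cartesian product of per-parameter value lists.
#' Axes are named after [model_parameters()] fields; the dedifferentiation
#' rate is given either as a single `k_DS` axis (constant rate) or as a pair
#' of `k_DS_early` / `k_DS_late` axes (two-segment schedule switching at a
#' fixed day, the hypoxia regime). A single-value axis pins that parameter.
#'
#' @param ... named numeric vectors, one per parameter axis. Each must be
#'   non-empty, sorted increasing and non-negative.
#' @return A `grid_spec` list with elements `axes` and `n_points`.
#' @examples
#' g <- grid_spec(alpha_S = 0.8, delta_S = 0.1, alpha_D = 0.9, delta_D = 0.1,
#'                k_SD = 0.1, k_DS = c(0.001, 0.002, 0.005, 0.01))
#' g$n_points
#' @export
grid_spec <- function(...) {
  axes <- list(...)
  allowed <- c("alpha_S", "delta_S", "alpha_D", "delta_D", "k_SD",
               "k_DS", "k_DS_early", "k_DS_late")
  if (is.null(names(axes)) || any(names(axes) == "")) {
    stop("all grid axes must be named")
  }
  bad <- setdiff(names(axes), allowed)
  if (length(bad)) stop("unknown grid axes: ", paste(bad, collapse = ", "))
  has_const <- "k_DS" %in% names(axes)
  has_phase <- all(c("k_DS_early", "k_DS_late") %in% names(axes))
  if (has_const && has_phase) stop("give either k_DS or k_DS_early/k_DS_late")
  if (!has_const && !has_phase) stop("a k_DS axis (or early/late pair) is required")
  need <- c("alpha_S", "delta_S", "alpha_D", "delta_D", "k_SD")
  miss <- setdiff(need, names(axes))
  if (length(miss)) stop("missing grid axes: ", paste(miss, collapse = ", "))
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (!length(v) || any(!is.finite(v)) || any(v < 0) || is.unsorted(v, strictly = FALSE)) {
      stop("axis ", nm, " must be a non-empty sorted non-negative vector")
    }
  }
  structure(list(axes = axes,
                 n_points = prod(vapply(axes, length, integer(1))),
                 two_phase = has_phase),
            class = "grid_spec")
}

#' Observed data for parameter fitting
#'
#' Fractions (not raw counts) are fitted: FACS reports proportions, and
#' absolute growth curves are confounded by condition-dependent growth
#' suppression. The optional mammosphere observation adds an absolute-growth
#' constraint through the stochastic assay.
#'
#' @param fractions data.frame with columns `time` (days), `fraction`
#'   (observed biomarker-positive fraction in `[0, 1]`), and optionally `n`
#'   (FACS events per timepoint).
#' @param mammosphere optional named vector `c(positives = , wells = )` of
#'   mammosphere assay counts.
#' @return A `fit_data` object.
#' @export
fit_data <- function(fractions, mammosphere = NULL) {
  stopifnot(is.data.frame(fractions),
            all(c("time", "fraction") %in% names(fractions)))
  if (any(fractions$time < 0)) stop("observation times must be non-negative")
  if (any(fractions$fraction < 0 | fractions$fraction > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  fractions <- fractions[order(fractions$time), , drop = FALSE]
  if (!is.null(mammosphere)) {
    stopifnot(all(c("positives", "wells") %in% names(mammosphere)),
              mammosphere[["wells"]] >= 1,
              mammosphere[["positives"]] >= 0,
              mammosphere[["positives"]] <= mammosphere[["wells"]])
  }
  structure(list(fractions = fractions, mammosphere = mammosphere),
            class = "fit_data")
}

# model_parameters from a named grid point (1-row list/vector), two-segment
# k_DS when early/late values are present
params_from_point <- function(point, switch_day = 3) {
  point <- as.list(point)
  kds <- if (!is.null(point$k_DS_early)) {
    cbind(start = c(0, switch_day), rate = c(point$k_DS_early, point$k_DS_late))
  } else {
    point$k_DS
  }
  model_parameters(alpha_S = point$alpha_S, delta_S = point$delta_S,
                   alpha_D = point$alpha_D, delta_D = point$delta_D,
                   k_SD = point$k_SD, k_DS = kds)
}

#' Tolerance-band loss of a parameter set against observed data
#'
#' The default loss is the Chebyshev (maximum absolute) residual: the largest
#' absolute deviation between the deterministic model fraction (from
#' [solve_deterministic()], starting from a pure biomarker-negative
#' population) and the observed fraction over all timepoints, combined by
#' maximum with the absolute deviation between the in-silico mammosphere rate
#' (from [simulate_mammosphere_rate()] at a fixed seed, so the search uses
#' common random numbers) and the observed rate, when a mammosphere
#' observation and protocol are supplied. A sup-norm residual is the natural
#' loss for accept-all-within-a-tolerance-band estimation; `method = "sse"`
#' switches to the sum of squared residuals.
#'
#' A model whose deterministic solution overflows gets infinite loss.
#'
#' `method = "max_z"` standardises each residual on the variance-stabilised
#' (arcsine square-root) scale before taking the maximum: a fraction residual
#' becomes `2 sqrt(n) |asin(sqrt(f_obs)) - asin(sqrt(f_mod))|`, which is a
#' standard-normal deviate under binomial sampling regardless of the fraction
#' itself, and the mammosphere residual is standardised analogously with the
#' well and run counts. The tolerance is then expressed in standard-error
#' units, which keeps small early-time fractions informative instead of
#' letting the largest-variance timepoint set a common absolute band.
#'
#' @param params a [model_parameters()] object.
#' @param data a [fit_data()] object.
#' @param proto optional [mammosphere_protocol()]; `NULL` disables the
#'   mammosphere term even when the data carry counts.
#' @param seed optional override of the protocol's seed.
#' @param method `"max"` (Chebyshev, default), `"sse"`, or `"max_z"`
#'   (Chebyshev on standardised residuals).
#' @return non-negative scalar loss; deterministic given the seed.
#' @export
loss <- function(params, data, proto = NULL, seed = NULL,
                 method = c("max", "sse", "max_z")) {
  stopifnot(inherits(params, "model_parameters"), inherits(data, "fit_data"))
  method <- match.arg(method)
  times <- sort(unique(c(0, data$fractions$time)))
  traj <- tryCatch(
    solve_deterministic(population_state(0, S = 0, D = 1), params, times),
    error = function(e) NULL
  )
  if (is.null(traj)) return(Inf)
  f <- suppressWarnings(fraction_positive(traj))
  fmod <- f[match(data$fractions$time, traj$t)]
  if (anyNA(fmod)) return(Inf)
  fobs <- data$fractions$fraction
  ang <- function(p) asin(sqrt(pmin(pmax(p, 0), 1)))
  if (method == "max_z") {
    if (is.null(data$fractions$n)) {
      stop("max_z loss requires a FACS sample size column `n` in the data")
    }
    resid <- 2 * sqrt(data$fractions$n) * abs(ang(fmod) - ang(fobs))
  } else {
    resid <- abs(fmod - fobs)
  }
  if (!is.null(proto) && !is.null(data$mammosphere)) {
    if (!is.null(seed)) proto$seed <- as.integer(seed)
    wells <- data$mammosphere[["wells"]]
    rate_obs <- data$mammosphere[["positives"]] / wells
    rate_mod <- simulate_mammosphere_rate(params, proto)$rate
    r_resid <- if (method == "max_z") {
      abs(ang(rate_mod) - ang(rate_obs)) /
        sqrt(1 / (4 * wells) + 1 / (4 * proto$n_runs))
    } else {
      abs(rate_mod - rate_obs)
    }
    resid <- c(resid, r_resid)
  }
  if (method == "sse") sum(resid^2) else max(resid)
}

#' Brute-force grid search with tolerance-band acceptance
#'
#' Evaluates the loss at every point of the Cartesian grid and accepts all
#' parameter sets whose loss does not exceed the tolerance. No best point is
#' selected: the estimate is the per-parameter mean over all accepted sets,
#' reported with the standard deviation over those sets. The result is
#' invariant to the enumeration order of the grid.
#'
#' @param grid a [grid_spec()].
#' @param data a [fit_data()] object.
#' @param tolerance positive acceptance tolerance on the loss.
#' @param proto optional [mammosphere_protocol()] for the mammosphere loss
#'   term (common seed across grid points).
#' @param seed optional protocol seed override.
#' @param switch_day switch day of the two-segment `k_DS` schedule when the
#'   grid has `k_DS_early` / `k_DS_late` axes (default 3).
#' @param method loss functional, see [loss()].
#' @return A `fit_result` list: `accepted` (data.frame of accepted points
#'   with their losses), `means` and `sds` (named per-axis summaries over the
#'   accepted sets, `NA` when nothing was accepted), `n_accepted`, `n_grid`,
#'   `tolerance`, `min_loss`, `switch_day`.
#' @export
brute_force_search <- function(grid, data, tolerance, proto = NULL,
                               seed = NULL, switch_day = 3,
                               method = c("max", "sse", "max_z")) {
  stopifnot(inherits(grid, "grid_spec"), inherits(data, "fit_data"))
  if (is.na(tolerance) || tolerance <= 0) stop("tolerance must be positive")
  method <- match.arg(method)
  points <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  losses <- vapply(seq_len(nrow(points)), function(i) {
    p <- params_from_point(points[i, , drop = FALSE], switch_day)
    loss(p, data, proto = proto, seed = seed, method = method)
  }, numeric(1))
  ok <- losses <= tolerance
  accepted <- points[ok, , drop = FALSE]
  accepted$loss <- losses[ok]
  rownames(accepted) <- NULL
  axis_names <- names(grid$axes)
  if (any(ok)) {
    means <- vapply(axis_names, function(nm) mean(accepted[[nm]]), numeric(1))
    sds <- vapply(axis_names, function(nm) stats::sd(accepted[[nm]]), numeric(1))
    sds[is.na(sds)] <- 0   # single accepted set: SD defined as 0
  } else {
    means <- stats::setNames(rep(NA_real_, length(axis_names)), axis_names)
    sds <- means
  }
  structure(list(accepted = accepted, means = means, sds = sds,
                 n_accepted = sum(ok), n_grid = nrow(points),
                 tolerance = tolerance, min_loss = min(losses),
                 switch_day = switch_day),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Brute-force grid fit: %d of %d grid points within tolerance %g\n",
              x$n_accepted, x$n_grid, x$tolerance))
  if (x$n_accepted == 0) {
    cat(sprintf("  no fit within tolerance; minimum loss %g\n", x$min_loss))
  } else {
    for (nm in names(x$means)) {
      cat(sprintf("  %-10s mean %.5g  sd %.5g\n", nm, x$means[[nm]], x$sds[[nm]]))
    }
    if (!is.null(x$kds_ratio)) {
      cat(sprintf("  late/early dedifferentiation ratio: %.4g\n", x$kds_ratio))
    }
  }
  invisible(x)
}

#' Fit a two-phase dedifferentiation rate
#'
#' Joint brute-force search over a grid with separate early and late
#' dedifferentiation axes (`k_DS_early` before `switch_day`, `k_DS_late`
#' after), as used to quantify the hypoxia-induced plasticity switch. The
#' headline statistic is the ratio of the accepted-set means,
#' `mean(k_DS_late) / mean(k_DS_early)`.
#'
#' @inheritParams brute_force_search
#' @param data_hypoxia a [fit_data()] time course observed under the
#'   switching condition.
#' @return A `fit_result` with an additional `kds_ratio` field (infinite,
#'   with a warning, when the mean early rate is 0).
#' @export
fit_two_phase_dedifferentiation <- function(grid, data_hypoxia, switch_day = 3,
                                            tolerance = 0.05, proto = NULL,
                                            seed = NULL,
                                            method = c("max", "sse", "max_z")) {
  if (!grid$two_phase) {
    stop("grid must have k_DS_early and k_DS_late axes")
  }
  fit <- brute_force_search(grid, data_hypoxia, tolerance = tolerance,
                            proto = proto, seed = seed,
                            switch_day = switch_day, method = method)
  if (fit$n_accepted > 0) {
    early <- fit$means[["k_DS_early"]]
    late <- fit$means[["k_DS_late"]]
    if (early == 0) {
      warning("mean early dedifferentiation rate is 0; ratio infinite")
      fit$kds_ratio <- Inf
    } else {
      fit$kds_ratio <- late / early
    }
  } else {
    fit$kds_ratio <- NA_real_
  }
  fit
}

#' Serialise a fit result as structured text
#'
#' Writes a summary block (`# key: value` comment lines) followed by the CSV
#' table of accepted parameter sets.
#'
#' @param fit a `fit_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_accepted: %d", fit$n_accepted), con)
  writeLines(sprintf("# n_grid: %d", fit$n_grid), con)
  writeLines(sprintf("# tolerance: %g", fit$tolerance), con)
  writeLines(sprintf("# min_loss: %g", fit$min_loss), con)
  if (!is.null(fit$kds_ratio)) {
    writeLines(sprintf("# kds_late_early_ratio: %g", fit$kds_ratio), con)
  }
  for (nm in names(fit$means)) {
    writeLines(sprintf("# mean_%s: %g", nm, fit$means[[nm]]), con)
    writeLines(sprintf("# sd_%s: %g", nm, fit$sds[[nm]]), con)
  }
  utils::write.csv(fit$accepted, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
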