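#' Model parameters for the two-compartment stem-cell plasticity model
#'
#' The model tracks two phenotypic compartments: biomarker-positive, stem-like
#' cells (S, e.g. GD2+) and biomarker-negative, differentiated cells (D). Each
#' compartment self-replicates and dies at first-order rates, and cells switch
#' phenotype in both directions. The dedifferentiation rate `k_DS` (non-stem to
#' stem conversion) may be a piecewise-constant schedule in time, which is how a
#' hypoxia-induced plasticity switch around day 3 is encoded.
#'
#' All rates are per day; time is measured in days throughout.
#'
#' @param alpha_S division rate of stem-like cells (per day).
#' @param delta_S death rate of stem-like cells (per day).
#' @param alpha_D division rate of differentiated cells (per day).
#' @param delta_D death rate of differentiated cells (per day).
#' @param k_SD differentiation rate, S to D (per day).
#' @param k_DS dedifferentiation rate, D to S (per day). Either a single
#'   non-negative number (constant rate) or a two-column matrix / data.frame
#'   `cbind(start, rate)` of piecewise-constant segments whose start times are
#'   strictly increasing and begin at 0.
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters(alpha_S = 0.4, delta_S = 0.1, alpha_D = 0.5,
#'                       delta_D = 0.1, k_SD = 0.05, k_DS = 0.01)
#' ph <- model_parameters(0.4, 0.05, 0.45, 0.05, 0.1,
#'                        k_DS = cbind(start = c(0, 3), rate = c(0.002, 0.02)))
#' kds_at(ph, c(2, 4))
#' @export
model_parameters <- function(alpha_S, delta_S, alpha_D, delta_D, k_SD, k_DS) {
  rates <- c(alpha_S = alpha_S, delta_S = delta_S, alpha_D = alpha_D,
             delta_D = delta_D, k_SD = k_SD)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and non-negative")
  }
  kds <- as_kds_schedule(k_DS)
  structure(
    list(alpha_S = alpha_S, delta_S = delta_S, alpha_D = alpha_D,
         delta_D = delta_D, k_SD = k_SD, k_DS = kds),
    class = "model_parameters"
  )
}

# normalise k_DS input to a matrix with columns start, rate
as_kds_schedule <- function(k_DS) {
  if (is.data.frame(k_DS)) k_DS <- as.matrix(k_DS)
  if (is.numeric(k_DS) && is.null(dim(k_DS))) {
    if (length(k_DS) != 1L) stop("scalar k_DS must have length 1")
    k_DS <- cbind(start = 0, rate = k_DS)
  }
  if (!is.matrix(k_DS) || ncol(k_DS) != 2L) {
    stop("k_DS must be a scalar or a two-column (start, rate) matrix")
  }
  colnames(k_DS) <- c("start", "rate")
  if (any(!is.finite(k_DS))) stop("k_DS schedule must be finite")
  if (any(k_DS[, "rate"] < 0)) stop("k_DS rates must be non-negative")
  if (k_DS[1, "start"] != 0) stop("first k_DS segment must start at time 0")
  if (nrow(k_DS) > 1L && any(diff(k_DS[, "start"]) <= 0)) {
    stop("k_DS segment start times must be strictly increasing")
  }
  k_DS
}

#' Evaluate the dedifferentiation rate schedule at given times
#'
#' @param params a `model_parameters` object.
#' @param t numeric vector of times (days, >= 0).
#' @return numeric vector of `k_DS` values, one per time.
#' @export
kds_at <- function(params, t) {
  stopifnot(inherits(params, "model_parameters"))
  if (any(t < 0)) stop("times must be non-negative")
  seg <- findInterval(t, params$k_DS[, "start"])
  unname(params$k_DS[seg, "rate"])
}

# TRUE when k_DS has a single constant segment
kds_is_constant <- function(params) nrow(params$k_DS) == 1L

#' @export
print.model_parameters <- function(x, ...) {
  cat("Two-compartment plasticity model parameters (per day):\n")
  cat(sprintf("  alpha_S = %g  delta_S = %g  (stem-like division / death)\n",
              x$alpha_S, x$delta_S))
  cat(sprintf("  alpha_D = %g  delta_D = %g  (differentiated division / death)\n",
              x$alpha_D, x$delta_D))
  cat(sprintf("  k_SD    = %g  (differentiation S -> D)\n", x$k_SD))
  if (kds_is_constant(x)) {
    cat(sprintf("  k_DS    = %g  (dedifferentiation D -> S, constant)\n",
                x$k_DS[1, "rate"]))
  } else {
    cat("  k_DS segments (dedifferentiation D -> S):\n")
    for (i in seq_len(nrow(x$k_DS))) {
      cat(sprintf("    from day %g: %g\n", x$k_DS[i, "start"], x$k_DS[i, "rate"]))
    }
  }
  invisible(x)
}

#' Population state of the two compartments
#'
#' @param t time in days (>= 0).
#' @param S stem-like (biomarker-positive) cell count, non-negative.
#' @param D differentiated (biomarker-negative) cell count, non-negative.
#' @return An object of class `population_state`.
#' @export
population_state <- function(t = 0, S, D) {
  if (!is.finite(t) || t < 0) stop("t must be finite and non-negative")
  if (!is.finite(S) || !is.finite(D) || S < 0 || D < 0) {
    stop("cell counts must be finite and non-negative")
  }
  structure(list(t = t, S = S, D = D), class = "population_state")
}
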