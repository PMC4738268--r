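# Independent oracles used across the suite. These never call the package's
# solvers: the ODE oracle is a segment-wise matrix exponential (Matrix::expm),
# the master-equation oracle exponentiates the truncated transition-rate
# matrix by uniformization, and the Fisher oracle enumerates 2x2 tables with
# exact integer hypergeometric weights.

# exact solution of the piecewise-linear mean-field system
expm_oracle <- function(init, params, times) {
  starts <- params$k_DS[, "start"]
  rates <- params$k_DS[, "rate"]
  amat <- function(kds) {
    matrix(c(params$alpha_S - params$delta_S - params$k_SD, params$k_SD,
             kds, params$alpha_D - params$delta_D - kds), 2, 2)
  }
  y <- c(init$S, init$D)
  tcur <- init$t
  out <- matrix(NA_real_, length(times), 2, dimnames = list(NULL, c("S", "D")))
  for (j in seq_along(times)) {
    tj <- times[j]
    repeat {
      seg <- findInterval(tcur, starts)
      nxt <- if (seg < length(starts)) starts[seg + 1] else Inf
      tstop <- min(tj, nxt)
      if (tstop > tcur) {
        y <- as.vector(Matrix::expm(amat(rates[seg]) * (tstop - tcur)) %*% y)
      }
      tcur <- tstop
      if (tcur >= tj) break
    }
    out[j, ] <- y
  }
  out
}

# distribution of (S, D) at t_end on the truncated state space S + D <= cap,
# by uniformization of the (substochastic) truncated rate matrix; constant
# k_DS only. Returns a data.frame (S, D, prob). The caller must pick a system
# whose probability of ever reaching the cap is negligible.
cme_oracle <- function(init, params, t_end, cap, tol = 1e-12) {
  stopifnot(nrow(params$k_DS) == 1L)
  kds <- unname(params$k_DS[1, "rate"])
  states <- expand.grid(S = 0:cap, D = 0:cap)
  states <- states[states$S + states$D <= cap, ]
  rownames(states) <- NULL
  n <- nrow(states)
  id <- function(S, D) match(S * (cap + 2) + D, states$S * (cap + 2) + states$D)
  moves <- list(c(1, 0), c(-1, 0), c(-1, 1), c(0, 1), c(0, -1), c(1, -1))
  prop <- cbind(params$alpha_S * states$S, params$delta_S * states$S,
                params$k_SD * states$S, params$alpha_D * states$D,
                params$delta_D * states$D, kds * states$D)
  from <- integer(0); to <- integer(0); val <- numeric(0)
  for (ch in 1:6) {
    S2 <- states$S + moves[[ch]][1]
    D2 <- states$D + moves[[ch]][2]
    ok <- prop[, ch] > 0 & S2 >= 0 & D2 >= 0 & (S2 + D2) <= cap
    from <- c(from, which(ok))
    to <- c(to, id(S2[ok], D2[ok]))
    val <- c(val, prop[ok, ch])
  }
  # diagonal carries ALL outflow (incl. transitions leaving the truncation)
  Q <- Matrix::sparseMatrix(i = from, j = to, x = val, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - rowSums(prop)
  lambda <- max(rowSums(prop)) * 1.01 + 1e-9
  P <- Q / lambda
  Matrix::diag(P) <- Matrix::diag(P) + 1
  p <- numeric(n)
  p[id(init$S, init$D)] <- 1
  out <- numeric(n)
  k <- 0
  w <- stats::dpois(0, lambda * t_end)
  repeat {
    out <- out + w * p
    if (k > lambda * t_end && w < tol) break
    k <- k + 1
    p <- as.numeric(p %*% P)
    w <- stats::dpois(k, lambda * t_end)
    if (k > 100000) stop("uniformization failed to converge")
  }
  data.frame(S = states$S, D = states$D, prob = out)
}

# two-sided Fisher exact p by full enumeration with exact integer weights
# (products of binomial coefficients are exact in double precision for
# table totals <= 30)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c; N <- m + n
  if (m == 0 || n == 0 || K == 0 || K == N) return(1)
  k <- max(0, K - n):min(m, K)
  w <- choose(m, k) * choose(n, K - k)
  wobs <- choose(m, a) * choose(n, c)
  sum(w[w <= wobs]) / choose(N, K)
}

# chi-square goodness-of-fit of observed counts against expected
# probabilities, pooling cells with expected count < 5 into one bin;
# returns the p-value
chisq_gof <- function(obs_counts, probs) {
  n <- sum(obs_counts)
  exp_counts <- n * probs
  small <- exp_counts < 5
  if (any(small)) {
    obs_counts <- c(obs_counts[!small], sum(obs_counts[small]))
    exp_counts <- c(exp_counts[!small], sum(exp_counts[small]))
  }
  stat <- sum((obs_counts - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = length(obs_counts) - 1, lower.tail = FALSE)
}

# random constant-rate parameter set with rates bounded by `max_rate`
random_params <- function(max_rate = 2, piecewise = FALSE) {
  r <- stats::runif(6, 0, max_rate)
  kds <- if (piecewise) {
    cbind(start = c(0, 3), rate = stats::runif(2, 0, max_rate / 2))
  } else {
    r[6]
  }
  model_parameters(alpha_S = r[1], delta_S = r[2], alpha_D = r[3],
                   delta_D = r[4], k_SD = r[5], k_DS = kds)
}

# standard 1-2-5 logarithmic value list for dedifferentiation-rate axes
kds_axis_125 <- c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3,
                  1e-2, 2e-2, 5e-2, 0.1, 0.2, 0.5, 1)
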