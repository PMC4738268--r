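test_that("parameter validation enforces the model invariants", {
  expect_error(model_parameters(-0.1, 0, 0, 0, 0, 0), "non-negative")
  expect_error(model_parameters(1, 0, 0, 0, 0, Inf), "finite")
  expect_error(model_parameters(1, 0, 0, 0, 0,
                                cbind(start = c(1, 3), rate = c(0.1, 0.2))),
               "start at time 0")
  expect_error(model_parameters(1, 0, 0, 0, 0,
                                cbind(start = c(0, 0), rate = c(0.1, 0.2))),
               "strictly increasing")
  p <- model_parameters(1, 0, 0, 0, 0,
                        cbind(start = c(0, 3), rate = c(0.001, 0.01)))
  expect_equal(kds_at(p, c(0, 2.9, 3, 5)), c(0.001, 0.001, 0.01, 0.01))
})

test_that("ode_rhs matches the defining rate equations", {
  p0 <- model_parameters(0.7, 0.2, 0.3, 0.1, 0.05, 0.02)
  expect_equal(ode_rhs(population_state(0, 0, 0), p0), c(dS = 0, dD = 0))

  p1 <- model_parameters(0, 0, 0.5, 0, 0, 0)
  expect_equal(ode_rhs(population_state(0, 0, 100), p1), c(dS = 0, dD = 50))

  p2 <- model_parameters(0.4, 0.1, 0.5, 0.1, 0.05, 0.01)
  expect_equal(ode_rhs(population_state(0, 10, 90), p2),
               c(dS = 3.4, dD = 35.6))
})

test_that("ode_rhs is linear in the state", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    s1 <- stats::runif(2, 0, 100)
    s2 <- stats::runif(2, 0, 100)
    a <- stats::runif(1, 0, 3)
    lhs <- ode_rhs(population_state(0, a * s1[1] + s2[1], a * s1[2] + s2[2]), p)
    rhs <- a * ode_rhs(population_state(0, s1[1], s1[2]), p) +
      ode_rhs(population_state(0, s2[1], s2[2]), p)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("frozen and decoupled systems solve exactly", {
  frozen <- model_parameters(0, 0, 0, 0, 0, 0)
  tr <- solve_deterministic(population_state(0, 5, 7), frozen, 0:10)
  expect_equal(tr$S, rep(5, 11))
  expect_equal(tr$D, rep(7, 11))

  dec <- model_parameters(0.3, 0, 0.5, 0, 0, 0)
  tr <- solve_deterministic(population_state(0, 2, 3), dec, seq(0, 4, 0.5))
  expect_equal(tr$S, 2 * exp(0.3 * tr$t), tolerance = 1e-8)
  expect_equal(tr$D, 3 * exp(0.5 * tr$t), tolerance = 1e-8)

  expect_error(solve_deterministic(population_state(0, 1, 1), dec, c(0, 2, 2)),
               "strictly increasing")
})

test_that("numerical solution matches the matrix-exponential oracle", {
  set.seed(21)
  for (i in 1:25) {
    p <- random_params(max_rate = 2, piecewise = i %% 2 == 0)
    init <- population_state(0, stats::runif(1, 1, 50), stats::runif(1, 1, 50))
    times <- seq(0, 20, length.out = 9)
    num <- solve_deterministic(init, p, times)
    ora <- expm_oracle(init, p, times)
    scale <- pmax(abs(ora[, "S"]), abs(ora[, "D"]), 1e-12)
    rel <- pmax(abs(num$S - ora[, "S"]), abs(num$D - ora[, "D"])) / scale
    expect_lt(max(rel), 1e-8)
  }
})

test_that("fraction_positive computes S/(S+D) and flags extinction", {
  tr <- data.frame(t = 0:2, S = c(0, 50, 0), D = c(100, 50, 0))
  expect_warning(f <- fraction_positive(tr), "extinct")
  expect_equal(f, c(0, 0.5, NA))

  scn <- scenario("hypoxia")
  tr <- solve_deterministic(population_state(0, 0, 1), scn$params, 0:8)
  f <- fraction_positive(tr)
  expect_equal(f, tr$S / (tr$S + tr$D))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("fraction dynamics follow the Riccati equation", {
  set.seed(31)
  for (i in 1:10) {
    p <- random_params(max_rate = 1)
    kds <- unname(p$k_DS[1, "rate"])
    dg <- (p$alpha_S - p$delta_S) - (p$alpha_D - p$delta_D)
    h <- 1e-4
    tr <- solve_deterministic(population_state(0, 3, 17), p,
                              c(0, 2 - h, 2, 2 + h, 3))
    f <- fraction_positive(tr)
    dfdt_num <- (f[4] - f[2]) / (2 * h)
    f2 <- f[3]
    dfdt_an <- kds * (1 - f2) - p$k_SD * f2 + dg * f2 * (1 - f2)
    expect_equal(dfdt_num, dfdt_an, tolerance = 1e-4)
  }
})

test_that("steady-state fraction: closed form, limits and monotonicity", {
  # no influx to S and S outgrown: equilibrium at zero
  p <- model_parameters(0.3, 0.1, 0.9, 0.1, 0.1, 0)
  expect_equal(steady_state_fraction(p), 0)
  # symmetric rates with equal net growth
  p <- model_parameters(0.5, 0.1, 0.5, 0.1, 0.2, 0.2)
  expect_equal(steady_state_fraction(p), 0.5)
  # piecewise schedules are rejected
  ph <- model_parameters(0.5, 0.1, 0.5, 0.1, 0.2,
                         cbind(start = c(0, 3), rate = c(0.1, 0.2)))
  expect_error(steady_state_fraction(ph), "single segment")
  # long-time integration converges to the closed form (bounded growth so
  # the trajectory stays finite over 200 days)
  set.seed(41)
  for (i in 1:5) {
    r <- stats::runif(4, 0, 0.5)
    p <- model_parameters(alpha_S = r[1], delta_S = r[1] + 0.05,
                          alpha_D = r[2], delta_D = r[2] + 0.1,
                          k_SD = r[3] + 0.01, k_DS = r[4] + 0.01)
    tr <- solve_deterministic(population_state(0, 1, 99), p, c(0, 100, 200))
    f_end <- fraction_positive(tr)[3]
    expect_equal(f_end, steady_state_fraction(p), tolerance = 1e-6)
  }
  # non-decreasing in k_DS
  fs <- vapply(c(0, 0.001, 0.01, 0.05, 0.2, 1),
               function(k) steady_state_fraction(
                 model_parameters(0.4, 0.1, 0.5, 0.1, 0.1, k)),
               numeric(1))
  expect_true(all(diff(fs) >= 0))
})

test_that("fraction rises monotonically from a pure negative start", {
  scn <- scenario("normoxia")   # stem-like compartment at growth disadvantage
  tr <- solve_deterministic(population_state(0, 0, 1), scn$params,
                            seq(0, 30, 0.5))
  f <- fraction_positive(tr)
  expect_true(all(diff(f) >= -1e-12))
  expect_lt(f[length(f)], steady_state_fraction(scn$params) + 1e-6)
})

test_that("trajectories round-trip through delimited text", {
  p <- model_parameters(0.4, 0.1, 0.5, 0.1, 0.05, 0.01)
  tr <- solve_deterministic(population_state(0, 10, 90), p, 0:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  expect_identical(readLines(path, n = 1), "t,S,D,f")
  back <- read_trajectory(path)
  expect_equal(back$S, tr$S, tolerance = 1e-6)
  expect_equal(back$f, fraction_positive(tr), tolerance = 1e-6)
})
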