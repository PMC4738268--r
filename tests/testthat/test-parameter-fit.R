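toy_grid <- function() {
  grid_spec(alpha_S = 0.4, delta_S = 0.1, alpha_D = c(0.45, 0.9),
            delta_D = 0.1, k_SD = c(0.05, 0.1),
            k_DS = c(0.002, 0.02))
}

noiseless_data <- function(params, days = 0:8, n = 10000L) {
  tr <- solve_deterministic(population_state(0, 0, 1), params,
                            sort(unique(c(0, days))))
  f <- fraction_positive(tr)[match(days, tr$t)]
  fit_data(data.frame(time = days, fraction = f, n = n))
}

test_that("grid specification validates axes and reports the product size", {
  g <- toy_grid()
  expect_equal(g$n_points, 8)
  expect_false(g$two_phase)
  expect_error(grid_spec(alpha_S = 1), "k_DS")
  expect_error(grid_spec(alpha_S = 1, delta_S = 0, alpha_D = 1, delta_D = 0,
                         k_SD = 0.1, k_DS = c(0.2, 0.1)), "sorted")
  expect_error(grid_spec(alpha_S = 1, delta_S = 0, alpha_D = 1, delta_D = 0,
                         k_SD = 0.1, k_DS = 0.1, bogus = 1), "unknown")
})

test_that("loss vanishes on self-generated noiseless data", {
  p <- model_parameters(0.4, 0.1, 0.45, 0.1, 0.1, 0.02)
  d <- noiseless_data(p)
  expect_lt(loss(p, d), 1e-8)
  expect_lt(loss(p, d, method = "max_z"), 1e-4)

  # a model with no dedifferentiation and a pure negative start stays at
  # fraction zero, matching all-zero observations exactly
  p0 <- model_parameters(0.4, 0.1, 0.45, 0.1, 0.1, 0)
  d0 <- fit_data(data.frame(time = 0:5, fraction = rep(0, 6), n = 1000L))
  expect_equal(loss(p0, d0), 0)
})

test_that("loss equals an independent residual recomputation", {
  set.seed(71)
  for (i in 1:5) {
    p <- random_params(max_rate = 0.8, piecewise = i %% 2 == 0)
    days <- 0:6
    obs <- stats::runif(length(days), 0, 0.3)
    obs[1] <- 0
    d <- fit_data(data.frame(time = days, fraction = obs, n = 5000L))
    tr <- solve_deterministic(population_state(0, 0, 1), p, days)
    fmod <- fraction_positive(tr)
    expect_equal(loss(p, d), max(abs(fmod - obs)), tolerance = 1e-10)
    zd <- 2 * sqrt(5000) * abs(asin(sqrt(fmod)) - asin(sqrt(obs)))
    expect_equal(loss(p, d, method = "max_z"), max(zd), tolerance = 1e-10)
  }
})

test_that("on-grid noiseless data recovers exactly the generating point", {
  g <- toy_grid()
  truth <- list(alpha_S = 0.4, delta_S = 0.1, alpha_D = 0.45, delta_D = 0.1,
                k_SD = 0.1, k_DS = 0.02)
  d <- noiseless_data(do.call(model_parameters, truth))
  fit <- brute_force_search(g, d, tolerance = 1e-6)
  expect_equal(fit$n_accepted, 1)
  for (nm in names(truth)) {
    expect_equal(fit$means[[nm]], truth[[nm]])
  }
  expect_equal(unname(fit$sds), rep(0, 6))
})

test_that("infinite tolerance accepts the full balanced grid", {
  g <- toy_grid()
  d <- noiseless_data(model_parameters(0.4, 0.1, 0.9, 0.1, 0.1, 0.002))
  fit <- brute_force_search(g, d, tolerance = Inf)
  expect_equal(fit$n_accepted, g$n_points)
  expect_equal(fit$means[["alpha_D"]], mean(c(0.45, 0.9)))
  expect_equal(fit$means[["k_DS"]], mean(c(0.002, 0.02)))
})

test_that("search equals exhaustive manual evaluation on a toy grid", {
  g <- toy_grid()
  d <- noiseless_data(model_parameters(0.4, 0.1, 0.45, 0.1, 0.05, 0.02))
  tol <- 0.02
  fit <- brute_force_search(g, d, tolerance = tol)
  manual <- expand.grid(g$axes, KEEP.OUT.ATTRS = FALSE)
  manual$loss <- vapply(seq_len(nrow(manual)), function(i) {
    loss(do.call(model_parameters, as.list(manual[i, ])), d)
  }, numeric(1))
  keep <- manual[manual$loss <= tol, ]
  expect_equal(fit$n_accepted, nrow(keep))
  expect_equal(sort(fit$accepted$loss), sort(keep$loss))
})

test_that("acceptance is monotone in tolerance and order-invariant", {
  g <- toy_grid()
  d <- noiseless_data(model_parameters(0.4, 0.1, 0.45, 0.1, 0.1, 0.002))
  fits <- lapply(c(0.005, 0.02, 0.1), function(tol) {
    brute_force_search(g, d, tolerance = tol)
  })
  sig <- function(fit) {
    df <- fit$accepted
    do.call(paste, c(df[order(df$loss, df$alpha_D, df$k_SD, df$k_DS), ],
                     sep = "/"))
  }
  expect_true(all(sig(fits[[1]]) %in% sig(fits[[2]])))
  expect_true(all(sig(fits[[2]]) %in% sig(fits[[3]])))

  # permuting the axis declaration order permutes enumeration, not the result
  g2 <- grid_spec(k_DS = c(0.002, 0.02), k_SD = c(0.05, 0.1),
                  delta_D = 0.1, alpha_D = c(0.45, 0.9),
                  delta_S = 0.1, alpha_S = 0.4)
  f1 <- brute_force_search(g, d, tolerance = 0.02)
  f2 <- brute_force_search(g2, d, tolerance = 0.02)
  expect_equal(f1$n_accepted, f2$n_accepted)
  expect_equal(f1$means[names(f2$means)], f2$means)
  expect_equal(sort(f1$accepted$loss), sort(f2$accepted$loss))
})

test_that("empty acceptance is an explicit failure state", {
  g <- toy_grid()
  d <- fit_data(data.frame(time = 0:4, fraction = rep(0.9, 5), n = 1000L))
  fit <- brute_force_search(g, d, tolerance = 0.01)
  expect_equal(fit$n_accepted, 0)
  expect_true(all(is.na(fit$means)))
  expect_true(is.finite(fit$min_loss))
  expect_gt(fit$min_loss, 0.01)
})

test_that("two-phase fit recovers flat and switching schedules", {
  axis <- c(0.002, 0.02, 0.2)
  base <- list(alpha_S = 0.4, delta_S = 0.1, alpha_D = 0.45, delta_D = 0.1,
               k_SD = 0.1)
  g <- do.call(grid_spec, c(base, list(k_DS_early = axis, k_DS_late = axis)))
  expect_true(g$two_phase)
  expect_error(fit_two_phase_dedifferentiation(toy_grid(),
                                               noiseless_data(random_params()),
                                               tolerance = 1),
               "k_DS_early")

  # no switch planted: equal early and late rates, ratio 1
  flat <- do.call(model_parameters, c(base, list(k_DS = 0.02)))
  fit <- fit_two_phase_dedifferentiation(g, noiseless_data(flat),
                                         tolerance = 1e-6)
  expect_equal(fit$kds_ratio, 1)

  # planted ten-fold switch at day 3
  sw <- do.call(model_parameters,
                c(base, list(k_DS = cbind(start = c(0, 3),
                                          rate = c(0.002, 0.02)))))
  fit <- fit_two_phase_dedifferentiation(g, noiseless_data(sw),
                                         tolerance = 1e-6)
  expect_equal(fit$n_accepted, 1)
  expect_equal(fit$kds_ratio, 10)

  # degenerate one-candidate grid: SDs all zero
  g1 <- do.call(grid_spec, c(base, list(k_DS_early = 0.002,
                                        k_DS_late = 0.02)))
  fit <- fit_two_phase_dedifferentiation(g1, noiseless_data(sw),
                                         tolerance = 1e-6)
  expect_equal(unname(fit$sds), rep(0, 7))
})

test_that("ratio recovery is unbiased under FACS sampling noise", {
  scn <- scenario("hypoxia")
  g <- grid_spec(alpha_S = scn$params$alpha_S, delta_S = scn$params$delta_S,
                 alpha_D = scn$params$alpha_D, delta_D = scn$params$delta_D,
                 k_SD = scn$params$k_SD,
                 k_DS_early = kds_axis_125, k_DS_late = kds_axis_125)
  ratios <- vapply(1:10, function(s) {
    scn_s <- scn
    scn_s$seed <- as.integer(5000 + s)
    tc <- generate_timecourse(scn_s)
    fit <- fit_two_phase_dedifferentiation(g, tc, tolerance = 3.5,
                                           method = "max_z")
    fit$kds_ratio
  }, numeric(1))
  expect_true(all(is.finite(ratios)))
  expect_lt(abs(mean(ratios) - 10), 3)
})

test_that("fit results serialise as structured text", {
  g <- toy_grid()
  d <- noiseless_data(model_parameters(0.4, 0.1, 0.45, 0.1, 0.1, 0.02))
  fit <- brute_force_search(g, d, tolerance = 1e-6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fit_result(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# n_accepted: 1$", lines)))
  expect_true(any(grepl("^# mean_k_DS: 0.02$", lines)))
  tab <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(tab), 1)
})
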