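# Cohort curves, features, sweeps, arm comparison and replicate bands.

test_that("cohort_curve is the exact average of step indicators", {
  cv <- cohort_curve(tibble::tibble(t_R = c(100, NA)),
                     t_grid = c(0, 99, 100, 200))
  expect_equal(cv$recurrence, c(0, 0, 0.5, 0.5))
  expect_equal(cv$survival, 1 - cv$recurrence)
  expect_equal(attr(cv, "n_patients"), 2)

  # all cures: flat at 1
  cv0 <- cohort_curve(tibble::tibble(t_R = rep(NA_real_, 5)),
                      t_grid = c(0, 10, 20))
  expect_true(all(cv0$survival == 1))

  # t = 0 intercept counts patients detectable at baseline
  cv1 <- cohort_curve(tibble::tibble(t_R = c(0, 0, NA, 50, NA, NA, NA, NA,
                                             NA, NA)),
                      t_grid = c(0, 50, 100))
  expect_equal(cv1$survival[1], 0.8)
  expect_error(cohort_curve(tibble::tibble(t_R = numeric(0))),
               class = "regrowr_domain_error")
})

test_that("curves are nonincreasing with the correct intercept and plateau", {
  d <- fig2_dist()
  m <- exp_model(lambda = 0.0008)
  out <- sample_cohort(d, 50, seed = 5) |> simulate_recurrence(m)
  cv <- cohort_curve(out, seq(0, 7300, 10))
  expect_true(all(diff(cv$survival) <= 0))
  expect_true(all(cv$survival >= 0 & cv$survival <= 1))
  expect_equal(cv$survival[1], 1 - mean(out$B0 >= m$omega_d))
  # plateau within 3 binomial SE of the exact cure fraction
  p <- fraction_below(d, m$eps_V)
  expect_lt(abs(cv$survival[nrow(cv)] - p), 3 * sqrt(p * (1 - p) / 50) + 1e-9)
})

test_that("curve_features reads intercept, plateau and drop proxy", {
  flat <- cohort_curve(tibble::tibble(t_R = rep(NA_real_, 4)),
                       t_grid = c(0, 100, 200))
  f <- curve_features(flat)
  expect_equal(f$y_intercept, 1)
  expect_equal(f$plateau, 1)
  expect_equal(f$drop_rate_proxy, 0)

  # 10% detectable at t = 0
  cv <- cohort_curve(tibble::tibble(t_R = c(0, rep(NA_real_, 9))),
                     t_grid = c(0, 100))
  expect_equal(curve_features(cv)$y_intercept, 0.9)
})

test_that("parameter sweeps reproduce the parameter-effect orderings", {
  d <- fig2_dist()
  m <- exp_model(lambda = 0.0015, eps_V = 0.01, omega_d = 0.056)
  grid <- seq(0, 7300, 5)

  sw_eps <- parameter_sweep(d, m, "eps_V", seq(0.010, 0.018, length.out = 5),
                            n = 300, seed = 17, t_grid = grid)
  expect_true(all(diff(sw_eps$plateau) >= 0))

  sw_om <- parameter_sweep(d, m, "omega_d", seq(0.018, 0.056, length.out = 5),
                           n = 300, seed = 17, t_grid = grid)
  expect_true(all(diff(sw_om$y_intercept) >= 0))

  sw_lam <- parameter_sweep(d, m, "lambda", seq(0.0008, 0.018, length.out = 5),
                            n = 300, seed = 17, t_grid = grid)
  expect_true(all(diff(sw_lam$drop_rate_proxy) <= 0))

  # common random numbers: curves at the baseline value match a direct run
  direct <- cohort_curve(
    simulate_recurrence(sample_cohort(d, 300, seed = 17), m), grid)
  expect_equal(sw_eps$curve[[1]]$survival, direct$survival)

  expect_error(
    parameter_sweep(d, m, "eps_V", c(0.01, 0.06), n = 10, seed = 1),
    regexp = "sweep point", class = "regrowr_config_error")
})

test_that("compare_arms uses common random numbers and orders plateaus", {
  m <- exp_model()
  spec <- list(dist = fig2_dist(), model = m, n = 100)
  same <- compare_arms(spec, spec, seed = 23, t_grid = seq(0, 7300, 10))
  expect_true(all(same$deltas$delta[1:2] == 0))

  a1 <- list(dist = burden_dist("mean_logsd", 0.03, 1.0), model = m, n = 200)
  a2 <- list(dist = burden_dist("mean_logsd", 0.05, 1.0), model = m, n = 200)
  cmp <- compare_arms(a1, a2, seed = 23, t_grid = seq(0, 7300, 10))
  pl <- cmp$deltas[cmp$deltas$feature == "plateau", ]
  expect_gt(pl$arm1, pl$arm2)  # more effective treatment, higher asymptote

  # an arm entirely above the detection threshold is flat at zero
  hot <- list(dist = burden_dist("mean_logsd", 5, 0.05), model = m, n = 50)
  cmp2 <- compare_arms(hot, a2, seed = 23, t_grid = seq(0, 7300, 10))
  arm1 <- dplyr::filter(cmp2$curves, arm == "arm1")
  expect_true(all(arm1$survival == 0))
})

test_that("replicate_band has the stated envelope semantics", {
  d <- fig2_dist()
  m <- exp_model()
  grid <- seq(0, 7300, 50)
  band <- replicate_band(d, m, n = 60, n_reps = 20, seed = 31, t_grid = grid)
  expect_true(all(band$lower95 <= band$mean + 1e-12))
  expect_true(all(band$mean <= band$upper95 + 1e-12))
  band2 <- replicate_band(d, m, n = 60, n_reps = 20, seed = 31, t_grid = grid)
  expect_identical(band$mean, band2$mean)   # reproducible

  # at n_reps = 2 the percentile envelope degenerates to min/max
  b2 <- replicate_band(d, m, n = 40, n_reps = 2, seed = 31, t_grid = grid)
  expect_true(all(b2$mean == (b2$lower95 + b2$upper95) / 2))
  # with two replicates the envelope is exactly their min and max
  cohorts2 <- vapply(1:2, function(r) {
    co <- tibble::tibble(B0 = regrowr:::with_seed(31, {
      rlnorm(80, d$meanlog, d$sdlog)
    })[((r - 1) * 40 + 1):(r * 40)])
    cohort_curve(simulate_recurrence(co, m), grid)$survival
  }, numeric(length(grid)))
  expect_equal(b2$lower95, pmin(cohorts2[, 1], cohorts2[, 2]))
  expect_equal(b2$upper95, pmax(cohorts2[, 1], cohorts2[, 2]))

  # degenerate all-cure distribution collapses the band to 1
  tiny <- burden_dist("mean_logsd", 1e-4, 0.05)
  b0 <- replicate_band(tiny, m, n = 20, n_reps = 3, seed = 1, t_grid = grid)
  expect_true(all(b0$mean == 1 & b0$lower95 == 1 & b0$upper95 == 1))

  # envelope width at the plateau ~ binomial percentile width
  drtog <- burden_dist("log_space", -8.0, 6.8)
  mr <- exp_model(lambda = 0.005, eps_V = 2.5e-4, omega_d = 0.4)
  br <- replicate_band(drtog, mr, n = 265, n_reps = 100, seed = 41,
                       t_grid = seq(0, 7300, 100))
  p <- fraction_below(drtog, 2.5e-4)
  width <- br$upper95[nrow(br)] - br$lower95[nrow(br)]
  expect_lt(abs(width - 2 * 1.96 * sqrt(p * (1 - p) / 265)),
            0.25 * 2 * 1.96 * sqrt(p * (1 - p) / 265))
})

test_that("without the viability term survival reaches zero for all laws", {
  d <- fig5_dist()
  for (law in c("exponential", "logistic", "gompertz")) {
    gl <- growth_law(law, 0.0009, K = if (law == "exponential") NULL else 13.8)
    m <- regrowth_model(gl, 0.015, 0.056, viability_term = FALSE)
    cohort <- sample_cohort(d, 30, seed = 3, K_dist = fig5_K_dist())
    cv <- cohort_curve(simulate_recurrence(cohort, m, horizon = 2e4),
                       seq(0, 2e4, 100))
    expect_equal(cv$survival[nrow(cv)], 0, info = law)
  }
})
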