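# Growth laws, net dynamics, the closed-form Bernoulli solution, and the
# adaptive ODE path.

test_that("growth_rate implements the three laws and their fixed points", {
  lam <- 1
  K <- 13.8
  V <- 0.056

  ge <- growth_law("exponential", lam)
  gl <- growth_law("logistic", lam, K)
  gg <- growth_law("gompertz", lam, K)

  expect_equal(growth_rate(ge, V), lam * V)
  # logistic attenuation at the detection threshold: 1 - V/K
  expect_equal(round(growth_rate(gl, V) / (lam * V), 3), 0.996)
  # Gompertz superexponential factor ln(K/V)
  expect_equal(growth_rate(gg, V) / (lam * V), log(K / V), tolerance = 1e-12)
  expect_equal(log(K / V), 5.507, tolerance = 1e-3)

  # V = 0 is the extinction fixed point for every law
  for (g in list(ge, gl, gg)) expect_identical(growth_rate(g, 0), 0)
  # Gompertz above K: negative rate, allowed
  expect_lt(growth_rate(gg, 2 * K), 0)

  expect_error(growth_rate(ge, -1), class = "regrowr_domain_error")
  expect_error(growth_law("exponential", -0.1), class = "regrowr_config_error")
  expect_error(growth_law("logistic", 1), class = "regrowr_config_error")
})

test_that("net_rate matches hand-evaluated threshold dynamics", {
  m <- exp_model(lambda = 0.0015, eps_V = 0.01, omega_d = 0.056)
  expect_equal(net_rate(m, 0.01), 0)                       # B = eps_V
  expect_equal(net_rate(m, 0.02), 3.0e-5, tolerance = 1e-12)
  expect_equal(net_rate(m, 0.005), -3.75e-6, tolerance = 1e-12)
})

test_that("net_rate has the Allee sign structure for all three laws", {
  eps_V <- 0.01
  omega_d <- 0.056
  K <- 13.8
  models <- list(
    regrowth_model(growth_law("exponential", 0.001), eps_V, omega_d),
    regrowth_model(growth_law("logistic", 0.001, K), eps_V, omega_d),
    regrowth_model(growth_law("gompertz", 0.001, K), eps_V, omega_d)
  )
  below <- seq(1e-4, eps_V - 1e-6, length.out = 25)
  above <- seq(eps_V + 1e-6, K * 0.99, length.out = 25)
  for (m in models) {
    expect_true(all(net_rate(m, below) < 0))
    expect_true(all(net_rate(m, above) > 0))
    expect_equal(net_rate(m, c(0, eps_V)), c(0, 0))
    # without the viability term the net rate is never negative on [0, K]
    m_off <- regrowth_model(m$growth, eps_V, omega_d, viability_term = FALSE)
    expect_true(all(net_rate(m_off, seq(0, K, length.out = 50)) >= 0))
  }
})

test_that("eps_V = 0 with the viability term on is a configuration error", {
  expect_error(
    regrowth_model(growth_law("exponential", 0.001), 0, 0.056),
    regexp = "viability_term = FALSE", class = "regrowr_config_error")
  # the eps_V -> 0 limit case is served by disabling the term
  m <- regrowth_model(growth_law("exponential", 0.001), 0, 0.056,
                      viability_term = FALSE)
  expect_equal(net_rate(m, 0.02), 0.001 * 0.02)
})

test_that("exponential_burden_at is the exact Bernoulli solution", {
  expect_equal(exponential_burden_at(0.01, 0.0015, 0.01, c(0, 100, 5000)),
               rep(0.01, 3))                                 # fixed point
  expect_equal(exponential_burden_at(0.02, 0.0015, 0.01, 0), 0.02)
  expect_equal(exponential_burden_at(0.02, 0.0015, 0.01, 330.958),
               0.056, tolerance = 1e-4)
  # cross-check against naive small-step Euler integration
  m <- exp_model()
  expect_equal(exponential_burden_at(0.02, 0.0015, 0.01, 200),
               euler_burden_at(m, 0.02, 200), tolerance = 1e-4)
  # at/beyond blow-up: domain error naming the blow-up time
  tstar <- (1 / 0.0015) * log((1 / 0.01) / (1 / 0.01 - 1 / 0.02))
  expect_error(exponential_burden_at(0.02, 0.0015, 0.01, tstar + 1),
               regexp = paste0("diverges at t\\* = ", floor(tstar)),
               class = "regrowr_domain_error")
})

test_that("exponential_recurrence_time handles all burden classes", {
  expect_equal(exponential_recurrence_time(0.056, 0.0015, 0.01, 0.056), 0)
  expect_equal(exponential_recurrence_time(0.02, 0.0015, 0.01, 0.056),
               331.0, tolerance = 1e-3)
  expect_true(is.na(exponential_recurrence_time(0.005, 0.0015, 0.01, 0.056)))
  expect_true(is.na(exponential_recurrence_time(0.01, 0.0015, 0.01, 0.056)))
  # diverges as B0 approaches eps_V from above
  expect_gt(exponential_recurrence_time(0.01005, 0.0015, 0.01, 0.056), 3000)
  expect_gt(exponential_recurrence_time(0.010001, 0.0015, 0.01, 0.056),
            exponential_recurrence_time(0.01005, 0.0015, 0.01, 0.056))
  expect_error(exponential_recurrence_time(-1, 0.0015, 0.01, 0.056),
               class = "regrowr_domain_error")
})

test_that("simulate_trajectory matches the closed form and handles blow-up", {
  m <- exp_model()
  # equilibrium trajectory stays put
  tr <- simulate_trajectory(m, 0.01, seq(0, 500, 50))
  expect_equal(tr$burden, rep(0.01, 11), tolerance = 1e-8)
  # decay below eps_V goes to zero
  tr <- simulate_trajectory(m, 0.005, seq(0, 20000, 1000))
  expect_true(all(diff(tr$burden) <= 0))
  expect_true(all(diff(tr$burden[1:5]) < 0))
  expect_lt(tr$burden[nrow(tr)], 1e-8)
  # growth above eps_V matches the closed form until truncation
  tgrid <- seq(0, 330, 10)
  tr <- simulate_trajectory(m, 0.02, tgrid)
  expect_equal(tr$burden, exponential_burden_at(0.02, 0.0015, 0.01, tgrid),
               tolerance = 1e-6)
  expect_false(attr(tr, "truncated"))
  # past the blow-up time the trajectory is truncated at the ceiling
  tstar <- (1 / 0.0015) * log((1 / 0.01) / (1 / 0.01 - 1 / 0.02))
  tr <- simulate_trajectory(m, 0.02, seq(0, ceiling(tstar) + 50, 1))
  expect_true(attr(tr, "truncated"))
  expect_lt(max(tr$time), tstar)
  expect_error(simulate_trajectory(m, Inf, c(0, 1)),
               class = "regrowr_domain_error")
})

test_that("ODE trajectories track the closed form over random parameters", {
  params <- random_exp_params(100, seed = 7)
  worst <- 0
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    m <- exp_model(p$lambda, p$eps_V, p$omega_d)
    tstar <- (1 / p$lambda) * log((1 / p$eps_V) / (1 / p$eps_V - 1 / p$B0))
    tgrid <- seq(0, 0.9 * tstar, length.out = 8)
    tr <- simulate_trajectory(m, p$B0, tgrid)
    cf <- exponential_burden_at(p$B0, p$lambda, p$eps_V, tgrid)
    worst <- max(worst, max(abs(tr$burden - cf) / cf))
  }
  expect_lt(worst, 1e-6)
})

test_that("logistic converges to exponential at large K; Gompertz dominates", {
  lam <- 0.0009
  eps_V <- 0.015
  omega_d <- 0.056
  B0s <- quantile_spaced_sample(fig5_dist(), 7, 0.1, 0.9)
  B0s <- B0s[B0s > eps_V & B0s < omega_d]
  t_exp <- exponential_recurrence_time(B0s, lam, eps_V, omega_d)

  K_big <- 1000 * omega_d
  m_log <- regrowth_model(growth_law("logistic", lam, K_big), eps_V, omega_d)
  t_log <- vapply(B0s, function(b) patient_recurrence_time(b, m_log)$t_R,
                  numeric(1))
  expect_true(all(abs(t_log - t_exp) / t_exp < 0.01))

  K <- 13.8  # K/e well above omega_d: superexponential over the whole transit
  m_gom <- regrowth_model(growth_law("gompertz", lam, K), eps_V, omega_d)
  t_gom <- vapply(B0s, function(b) patient_recurrence_time(b, m_gom)$t_R,
                  numeric(1))
  expect_true(all(t_gom < t_exp))
})
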