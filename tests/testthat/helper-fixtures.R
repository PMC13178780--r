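# Shared fixtures: baseline models, distributions and independent oracles.

exp_model <- function(lambda = 0.0015, eps_V = 0.01, omega_d = 0.056,
                      viability = TRUE) {
  regrowth_model(growth_law("exponential", lambda), eps_V, omega_d,
                 viability_term = viability)
}

fig2_dist <- function() burden_dist("arithmetic", 0.05, 0.06)
fig5_dist <- function() burden_dist("mean_logsd", 0.02, 0.5)
fig5_K_dist <- function() burden_dist("mean_logsd", 13.8, 0.5)

# Independent oracle 1: brute-force fixed-step Euler integration of the
# net dynamics (deliberately naive; small steps).
euler_burden_at <- function(model, B0, t_end, K = NULL, dt = 0.01) {
  B <- B0
  steps <- ceiling(t_end / dt)
  dt <- t_end / steps
  for (i in seq_len(steps)) B <- B + dt * net_rate(model, B, K = K)
  B
}

# Independent oracle 2: recurrence time by quadrature of
# dt = dB / [f(B) (B/eps_V - 1)] from B0 to omega_d.
quadrature_recurrence_time <- function(model, B0, K = NULL) {
  integrate(function(B) {
    1 / net_rate(model, B, K = K)
  }, B0, model$omega_d, rel.tol = 1e-10)$value
}

random_exp_params <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      lambda = runif(n, 5e-4, 5e-3),
      eps_V = runif(n, 0.005, 0.02),
      omega_d = runif(n, 0.04, 0.4)
    ) |>
      dplyr::mutate(B0 = eps_V + (omega_d - eps_V) * runif(n, 0.05, 0.95))
  })
}
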