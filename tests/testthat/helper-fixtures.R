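# shared fixtures: small, fast parameter sets and schedules

std_schedule <- function(t0 = 5, T = 10, n = 4) {
  switching_schedule(t0 = t0, half_period_T = T, n_cycles = n)
}

std_params <- function(sigma_sat = 1, alpha = 1.3, tau_s = 8, tau_r = 60,
                       t0 = 5) {
  sorption_params(sigma_sat, alpha, tau_s, tau_r, t0)
}

# randomized physical parameter draws used by the property tests
draw_params <- function(T = 10) {
  tau_s <- stats::runif(1, 0.05, 5) * T
  tau_r <- stats::runif(1, 0.3, 10) * T
  if (abs(tau_r - tau_s) < 0.05 * T) tau_r <- tau_s + 0.5 * T
  list(sigma_sat = stats::runif(1, 0.5, 3),
       alpha = stats::runif(1, 0.3, 2),
       tau_s = tau_s, tau_r = tau_r,
       t0 = stats::runif(1, 0, T))
}

# small fast generator config for pipeline tests: pure_vfa protocol is
# ~90 s at 20 Hz instead of 610 s at 100 Hz
fast_config <- function(seed = 1, ...) {
  generator_config(protocol = "pure_vfa", seed = seed, ...)
}
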