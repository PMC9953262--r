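#' Kinetic/viscoelastic parameter set for the sensor response model
#'
#' Bundles the parameters of the closed-form nanomechanical response model:
#' a two-exponential step response mixing a sorption (diffusion) channel with
#' time constant `tau_s` and a viscoelastic stress-relaxation channel with
#' time constant `tau_r`.
#'
#' @param sigma_sat Saturation amplitude of the signal (sensor output units,
#'   mV-equivalent). Must be >= 0.
#' @param alpha Dimensionless mixing weight between the sorption and
#'   relaxation exponentials. May exceed 1: for a receptor with unrelaxed
#'   modulus `E_U` above the relaxed modulus `E_R` and `tau_r > tau_s` the
#'   effective weight is `1 + (E_U/E_R - 1) * tau_r / (tau_r - tau_s) > 1`,
#'   producing the overshoot seen on glassy polymer films.
#' @param tau_s Diffusion (sorption/desorption) time constant in seconds,
#'   > 0.
#' @param tau_r Stress-relaxation time constant in seconds, > 0.
#' @param t0 Response onset time in seconds.
#' @param sign Response polarity, +1 or -1. Polarity is a wiring/bridge
#'   convention; the model is written positive-rising.
#'
#' @return An object of class `sorption_params`.
#' @export
sorption_params <- function(sigma_sat, alpha, tau_s, tau_r, t0 = 0,
                            sign = 1) {
  stopifnot(is.numeric(sigma_sat), length(sigma_sat) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(tau_s), length(tau_s) == 1L,
            is.numeric(tau_r), length(tau_r) == 1L,
            is.numeric(t0), length(t0) == 1L)
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  if (!is.finite(tau_r) || tau_r <= 0) stop("tau_r must be > 0")
  if (!is.finite(sigma_sat) || sigma_sat < 0) stop("sigma_sat must be >= 0")
  if (!is.finite(alpha)) stop("alpha must be finite")
  if (!is.finite(t0)) stop("t0 must be finite")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(sigma_sat = sigma_sat, alpha = alpha, tau_s = tau_s,
                 tau_r = tau_r, t0 = t0, sign = sign),
            class = "sorption_params")
}

#' @export
print.sorption_params <- function(x, ...) {
  cat(sprintf(
    "sorption_params: sigma_sat=%g alpha=%g tau_s=%gs tau_r=%gs t0=%gs sign=%+d\n",
    x$sigma_sat, x$alpha, x$tau_s, x$tau_r, x$t0, x$sign))
  invisible(x)
}

#' Valve switching schedule for injection/purge cycling
#'
#' Describes when the sample stream is switched onto and off the sensor.
#' Either give the equal-half-period form (`t0`, `half_period_T`,
#' `n_cycles`) for protocols like 10 s on / 10 s off, or an explicit
#' `switch_times` vector for unequal durations such as the silage protocol
#' (120 s sampling then 480 s purge). Switch states always alternate
#' starting with an injection.
#'
#' @param t0 First injection time (s).
#' @param half_period_T Duration of each injection and each purge (s);
#'   required unless `switch_times` is given.
#' @param n_cycles Number of injection/purge cycles (>= 1).
#' @param switch_times Optional strictly increasing numeric vector of switch
#'   times (s); odd entries start injections, even entries start purges.
#'
#' @return An object of class `switching_schedule` with elements
#'   `switch_times`, `states` (+1 inject, -1 purge), and, for the equal-T
#'   form, `t0`, `half_period_T`, `n_cycles`, plus `equal_T` flag.
#' @export
switching_schedule <- function(t0 = 0, half_period_T = NULL, n_cycles = NULL,
                               switch_times = NULL) {
  if (is.null(switch_times)) {
    if (is.null(half_period_T) || is.null(n_cycles))
      stop("give either (half_period_T, n_cycles) or switch_times")
    stopifnot(is.numeric(half_period_T), length(half_period_T) == 1L)
    if (half_period_T <= 0) stop("half_period_T must be > 0")
    n_cycles <- as.integer(n_cycles)
    if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1")
    st <- t0 + half_period_T * seq(0L, 2L * n_cycles - 1L)
    equal_T <- TRUE
  } else {
    st <- as.numeric(switch_times)
    if (length(st) < 1L) stop("switch_times must be non-empty")
    if (any(diff(st) <= 0)) stop("switch_times must be strictly increasing")
    t0 <- st[1L]
    durs <- diff(st)
    equal_T <- length(st) >= 2L &&
      all(abs(durs - durs[1L]) < 1e-9) && length(st) %% 2L == 0L
    half_period_T <- if (equal_T) durs[1L] else NA_real_
    n_cycles <- if (equal_T) length(st) %/% 2L else NA_integer_
  }
  states <- rep_len(c(1, -1), length(st))
  structure(list(switch_times = st, states = states, t0 = t0,
                 half_period_T = half_period_T, n_cycles = n_cycles,
                 equal_T = equal_T),
            class = "switching_schedule")
}

#' @export
print.switching_schedule <- function(x, ...) {
  if (isTRUE(x$equal_T)) {
    cat(sprintf("switching_schedule: t0=%gs, T=%gs, %d cycle(s)\n",
                x$t0, x$half_period_T, x$n_cycles))
  } else {
    cat(sprintf("switching_schedule: %d switches from %gs to %gs\n",
                length(x$switch_times), x$switch_times[1L],
                x$switch_times[length(x$switch_times)]))
  }
  invisible(x)
}

# Two-exponential step basis, zero for dt < 0.
# 1 - alpha*exp(-dt/tau_s) - (1-alpha)*exp(-dt/tau_r); when tau_s == tau_r
# the alpha terms collapse and the basis is 1 - exp(-dt/tau).
.step_basis <- function(dt, alpha, tau_s, tau_r) {
  out <- numeric(length(dt))
  pos <- dt >= 0
  d <- dt[pos]
  out[pos] <- 1 - alpha * exp(-d / tau_s) - (1 - alpha) * exp(-d / tau_r)
  out
}

#' Response to a single valve switch
#'
#' The basis function of the multi-cycle model: the signal a time `dt` after
#' a single injection onset,
#' `sign * sigma_sat * (1 - alpha*exp(-dt/tau_s) - (1-alpha)*exp(-dt/tau_r))`.
#' It is 0 at `dt = 0` and tends to `sign * sigma_sat` as `dt` grows.
#'
#' @param params A [sorption_params()] object.
#' @param dt Time since the switch (s), vectorized; values < 0 return 0.
#' @return Numeric vector of signal values.
#' @export
single_switch_response <- function(params, dt) {
  stopifnot(inherits(params, "sorption_params"))
  params$sign * params$sigma_sat *
    .step_basis(dt, params$alpha, params$tau_s, params$tau_r)
}

#' Multi-cycle injection/purge response (closed form)
#'
#' Piecewise closed-form response over `n` equal injection/purge cycles of
#' half-period `T`. Within the nth injection window the value is
#' `sigma_sat - sum_{i=0}^{2(n-1)} (-1)^i [sigma_sat*alpha*e^{-(t-t0-iT)/tau_s}
#' + sigma_sat*(1-alpha)*e^{-(t-t0-iT)/tau_r}]` (times `sign`); in the nth
#' purge window the same sum runs to `2n-1` with no leading `sigma_sat`.
#' All exponents are evaluated in the time-shifted form `-(t-t0-iT)/tau`,
#' which keeps every exponent non-positive inside a valid branch; the
#' algebraically equivalent product `e^{-(t-t0)/tau} * (e^{T/tau})^i`
#' overflows when `T >> tau` and is never formed. The response is continuous
#' at every switch time and is 0 for `t < t0`.
#'
#' After the last purge window the superposition tail (all switches active)
#' is returned, so curves recorded past the final cycle decay smoothly.
#'
#' @param params A [sorption_params()] object (its `t0` is ignored; the
#'   schedule's `t0` is used).
#' @param schedule An equal-T [switching_schedule()].
#' @param t Time (s), vectorized.
#' @return Numeric vector of signal values.
#' @export
multi_cycle_response <- function(params, schedule, t) {
  stopifnot(inherits(params, "sorption_params"),
            inherits(schedule, "switching_schedule"))
  if (!isTRUE(schedule$equal_T))
    stop("multi_cycle_response needs an equal-T schedule; ",
         "use superposition_response for unequal durations")
  T_ <- schedule$half_period_T
  t0 <- schedule$t0
  n <- schedule$n_cycles
  out <- numeric(length(t))
  rel <- t - t0
  # index of the last switch at or before t: floor(rel / T), capped at the
  # final switch (tail of the record keeps all 2n terms active)
  k <- pmin(floor(rel / T_), 2 * n - 1)
  active <- rel >= 0
  if (!any(active)) return(out)
  ka <- k[active]
  rel_a <- rel[active]
  sig <- params$sigma_sat
  acc <- numeric(sum(active))
  for (i in 0:(2 * n - 1)) {
    on <- ka >= i
    if (!any(on)) break
    d <- rel_a[on] - i * T_
    term <- sig * params$alpha * exp(-d / params$tau_s) +
      sig * (1 - params$alpha) * exp(-d / params$tau_r)
    acc[on] <- acc[on] + (-1)^i * term
  }
  # leading sigma_sat appears when an odd number of switches is active
  lead <- sig * (ka %% 2 == 0)
  out[active] <- params$sign * (lead - acc)
  out
}

#' General superposition response for alternating schedules
#'
#' Linear superposition of single-switch responses: each injection switch
#' adds `+f(t - tau_k)` and each purge switch adds `-f(t - tau_k)` where `f`
#' is [single_switch_response()]. Handles unequal injection/purge durations
#' (e.g. 120 s sampling / 480 s purge); reduces exactly to
#' [multi_cycle_response()] on equal-T schedules.
#'
#' @param params A [sorption_params()] object.
#' @param schedule A [switching_schedule()] (equal or unequal durations).
#' @param t Time (s), vectorized.
#' @param tau_s_desorb Optional desorption-phase diffusion time constant (s):
#'   purge-switch terms use this in place of `tau_s`, a phenomenological
#'   handle for dissociation-delayed desorption of acids in the presence of
#'   water. Default `NULL` uses `tau_s` throughout.
#' @return Numeric vector of signal values.
#' @export
superposition_response <- function(params, schedule, t, tau_s_desorb = NULL) {
  stopifnot(inherits(params, "sorption_params"),
            inherits(schedule, "switching_schedule"))
  st <- schedule$switch_times
  s <- schedule$states
  if (length(st) >= 2L && any(s[-1L] == s[-length(s)]))
    stop("schedule states must alternate")
  out <- numeric(length(t))
  for (kk in seq_along(st)) {
    dt <- t - st[kk]
    if (s[kk] < 0 && !is.null(tau_s_desorb)) {
      out <- out - params$sign * params$sigma_sat *
        .step_basis(dt, params$alpha, tau_s_desorb, params$tau_r)
    } else {
      out <- out + s[kk] * single_switch_response(params, dt)
    }
  }
  out
}

#' Analyte concentration in the receptor layer, single injection/purge
#'
#' First-order sorption kinetics for one injection from `t0` to `t3`:
#' `C(t) = Kp*Cg*(1 - e^{-(t-t0)/tau_s})` during injection and
#' `Kp*Cg*(1 - e^{-T/tau_s}) * e^{-(t-t3)/tau_s}` during the purge, with
#' `T = t3 - t0`; zero before `t0` and continuous at `t3`.
#'
#' @param Kp Partition coefficient (dimensionless, >= 0).
#' @param Cg Gas-phase analyte concentration (ppm, >= 0).
#' @param tau_s Diffusion time constant (s, > 0).
#' @param t0 Injection start (s).
#' @param t3 Injection end (s), > t0.
#' @param t Time (s), vectorized.
#' @return Concentration in the receptor layer (same units as `Kp*Cg`).
#' @export
concentration_profile <- function(Kp, Cg, tau_s, t0, t3, t) {
  if (t3 <= t0) stop("t3 must be > t0")
  if (Kp < 0 || Cg < 0) stop("Kp and Cg must be >= 0")
  if (tau_s <= 0) stop("tau_s must be > 0")
  T_ <- t3 - t0
  out <- numeric(length(t))
  rise <- t >= t0 & t < t3
  decay <- t >= t3
  out[rise] <- Kp * Cg * (1 - exp(-(t[rise] - t0) / tau_s))
  out[decay] <- Kp * Cg * (1 - exp(-T_ / tau_s)) * exp(-(t[decay] - t3) / tau_s)
  out
}

#' Rise/decay symmetry index
#'
#' Returns `exp(-T / tau_s)`, the carried-over fraction of the sorbed
#' analyte at the end of one half-period. Near 0 the decay mirrors the rise
#' (symmetric regime, fast desorption); near 1 material accumulates across
#' cycles (asymmetric regime, slow desorption).
#'
#' @param params A [sorption_params()] object (only `tau_s` is used), or a
#'   single numeric `tau_s`.
#' @param schedule An equal-T [switching_schedule()], or a single numeric
#'   half-period `T`.
#' @return Dimensionless score in (0, 1].
#' @export
symmetry_index <- function(params, schedule) {
  tau_s <- if (inherits(params, "sorption_params")) params$tau_s else params
  T_ <- if (inherits(schedule, "switching_schedule")) {
    if (!isTRUE(schedule$equal_T)) stop("symmetry_index needs an equal-T schedule")
    schedule$half_period_T
  } else schedule
  exp(-T_ / tau_s)
}

#' Per-cycle maxima of the multi-cycle response
#'
#' Maximizes the closed-form model over each injection window. For slow
#' desorbers (`tau_s` comparable to or larger than `T`) the carried-over
#' analyte makes the sequence grow cycle by cycle, converging geometrically;
#' for fast desorbers all peaks are equal.
#'
#' @param params A [sorption_params()] object.
#' @param schedule An equal-T [switching_schedule()] with `n_cycles >= 2`.
#' @param n_grid Grid density per window for the bracketing scan.
#' @return Numeric vector of length `n_cycles`: the maximum of
#'   `sign * response` over each injection window (closed at both ends).
#' @export
cycle_peaks <- function(params, schedule, n_grid = 512L) {
  stopifnot(inherits(schedule, "switching_schedule"), isTRUE(schedule$equal_T))
  if (schedule$n_cycles < 2L) stop("cycle_peaks needs n_cycles >= 2")
  T_ <- schedule$half_period_T
  f <- function(t) params$sign * multi_cycle_response(params, schedule, t)
  vapply(seq_len(schedule$n_cycles), function(nn) {
    a <- schedule$t0 + 2 * (nn - 1) * T_
    b <- a + T_
    grid <- seq(a, b, length.out = n_grid)
    v <- f(grid)
    i <- which.max(v)
    # refine around the grid maximum unless it sits on a window edge
    if (i > 1L && i < n_grid) {
      opt <- stats::optimize(f, lower = grid[i - 1L], upper = grid[i + 1L],
                             maximum = TRUE, tol = 1e-10)
      max(v[i], opt$objective)
    } else v[i]
  }, numeric(1))
}

#' Mixing weight implied by a viscoelastic modulus ratio
#'
#' For a receptor with relaxation modulus `E(t) = E_R + (E_U - E_R) *
#' exp(-t/tau_r)` driven by first-order sorption with time constant `tau_s`,
#' the hereditary (Boltzmann) integral collapses to the two-exponential step
#' basis with weight `alpha = 1 + (E_U/E_R - 1) * tau_r / (tau_r - tau_s)`.
#' Undefined at `tau_r == tau_s` (confluent case: the response carries a
#' `t * exp(-t/tau)` term that no finite `alpha` reproduces).
#'
#' @param e_ratio Modulus ratio `E_U / E_R` (>= 1 for physical films).
#' @param tau_s,tau_r Time constants (s); must differ.
#' @return The implied `alpha`.
#' @seealso [alpha_to_modulus_ratio()] for the inverse.
#' @export
modulus_ratio_to_alpha <- function(e_ratio, tau_s, tau_r) {
  if (tau_r == tau_s) stop("alpha is undefined at tau_r == tau_s (confluent case)")
  1 + (e_ratio - 1) * tau_r / (tau_r - tau_s)
}

#' Modulus ratio implied by a fitted mixing weight
#'
#' Inverse of [modulus_ratio_to_alpha()]:
#' `E_U/E_R = 1 + (alpha - 1) * (tau_r - tau_s) / tau_r`.
#'
#' @param alpha Fitted mixing weight.
#' @param tau_s,tau_r Time constants (s); must differ.
#' @return The implied `E_U / E_R`.
#' @export
alpha_to_modulus_ratio <- function(alpha, tau_s, tau_r) {
  if (tau_r == tau_s) stop("E_U/E_R is undefined at tau_r == tau_s")
  1 + (alpha - 1) * (tau_r - tau_s) / tau_r
}
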