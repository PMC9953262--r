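#' Viscoelastic receptor parameters for the numerical oracle
#'
#' Standard-linear-solid relaxation modulus `E(t) = E_R + (E_U - E_R) *
#' exp(-t/tau_r)` plus a gain mapping sorbed concentration to strain. Used
#' only by [ode_convolution_oracle()], the independent ground truth for the
#' closed-form model.
#'
#' @param E_U Unrelaxed (instantaneous) modulus, arbitrary units.
#' @param E_R Relaxed (long-time) modulus; requires `E_U >= E_R > 0`.
#' @param tau_r Relaxation time constant (s, > 0).
#' @param gain Proportionality constant from sorbed concentration to strain
#'   (> 0).
#' @return An object of class `viscoelastic_params`.
#' @export
viscoelastic_params <- function(E_U, E_R, tau_r, gain = 1) {
  if (!(E_U >= E_R && E_R > 0)) stop("need E_U >= E_R > 0")
  if (tau_r <= 0) stop("tau_r must be > 0")
  if (gain <= 0) stop("gain must be > 0")
  structure(list(E_U = E_U, E_R = E_R, tau_r = tau_r, gain = gain),
            class = "viscoelastic_params")
}

#' Numerical sorption-ODE / hereditary-integral oracle
#'
#' Independent ground truth for the closed-form response model, built from
#' the underlying physics with no shared algebra:
#' \enumerate{
#'   \item integrate the sorption ODE `dC/dt = (Kp*Cg*u(t) - C)/tau_s`
#'     where `u(t)` is the valve state (1 during injection, 0 during purge),
#'     by exact exponential stepping on a uniform grid aligned to the
#'     switch times;
#'   \item set the strain `eps(t) = gain * C(t)`;
#'   \item evaluate the Boltzmann hereditary integral
#'     `sigma(t) = integral of E(t-u) * eps'(u) du` by trapezoidal
#'     quadrature, with `eps'` from central differences and relaxation
#'     modulus `E(t) = E_R + (E_U - E_R) * exp(-t/tau_r)`.
#' }
#' For a single injection this collapses analytically to the
#' two-exponential basis with `sigma_sat = gain * Kp * Cg * E_R` and
#' `alpha = 1 + (E_U/E_R - 1) * tau_r / (tau_r - tau_s)` (see
#' [modulus_ratio_to_alpha()]); the oracle verifies that mapping rather
#' than assuming it. The quadrature handles `tau_r == tau_s` (confluent
#' case) without special-casing since nothing is divided by `tau_r - tau_s`.
#'
#' @param Kp,Cg,tau_s Sorption drive: partition coefficient, gas
#'   concentration and diffusion time constant (as in
#'   [concentration_profile()]).
#' @param visco A [viscoelastic_params()] object.
#' @param schedule A [switching_schedule()].
#' @param dt Integration step (s); must satisfy `dt <= tau_s/50` and
#'   `dt <= tau_r/50`. Accuracy is O(dt^2); use `tau/200` or finer when
#'   comparing to the closed form at 1e-5 relative.
#' @param eval_times Times (s) at which the stress is returned; defaults to
#'   a 200-point grid spanning the integration window.
#' @param t_end End of the integration window (s); defaults to the last
#'   switch plus five half-periods' worth of decay.
#' @return A [response_curve()] holding `eval_times` and the stress signal.
#' @export
ode_convolution_oracle <- function(Kp, Cg, tau_s, visco, schedule, dt,
                                   eval_times = NULL, t_end = NULL) {
  stopifnot(inherits(visco, "viscoelastic_params"),
            inherits(schedule, "switching_schedule"))
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (dt > tau_s / 50 || dt > visco$tau_r / 50)
    stop("integration step too coarse: need dt <= tau_s/50 and <= tau_r/50")
  st <- schedule$switch_times
  span <- if (length(st) >= 2L) diff(range(st)) else tau_s * 10
  if (is.null(t_end)) t_end <- st[length(st)] + span + 5 * tau_s
  t_start <- st[1L]

  # grid aligned to switch times so the drive is exactly piecewise constant
  # on steps and the strain kinks fall on nodes (keeps trapezoid O(dt^2))
  knots <- sort(unique(c(t_start, st[st <= t_end], t_end)))
  grid <- unlist(lapply(seq_len(length(knots) - 1L), function(j) {
    nseg <- max(2L, ceiling((knots[j + 1L] - knots[j]) / dt) + 1L)
    seq(knots[j], knots[j + 1L], length.out = nseg)[-1L]
  }))
  grid <- c(t_start, grid)
  h <- diff(grid)

  # drive state on each step (state at the left endpoint)
  u_of <- function(tt) {
    idx <- findInterval(tt, st)
    out <- numeric(length(tt))
    out[idx >= 1L] <- (schedule$states[pmax(idx, 1L)])[idx >= 1L] > 0
    out
  }
  u_step <- u_of(grid[-length(grid)] + h / 2)

  # exact exponential stepping of dC/dt = (Kp*Cg*u - C)/tau_s
  C <- numeric(length(grid))
  target <- Kp * Cg * u_step
  decay <- exp(-h / tau_s)
  for (i in seq_along(h)) {
    C[i + 1L] <- target[i] + (C[i] - target[i]) * decay[i]
  }

  eps <- visco$gain * C
  n <- length(grid)
  # strain-rate estimates with one-sided values at segment boundaries: the
  # strain has kinks at the switch times, so a node on a knot carries a
  # left and a right derivative (second-order one-sided differences);
  # smooth interior nodes use the central difference for both sides
  is_knot <- logical(n)
  is_knot[c(1L, n)] <- TRUE
  ki <- round(stats::approx(grid, seq_len(n), xout = knots,
                            method = "linear", rule = 2)$y)
  is_knot[ki] <- TRUE
  depsL <- numeric(n); depsR <- numeric(n)
  inner <- which(!is_knot)
  depsL[inner] <- (eps[inner + 1L] - eps[inner - 1L]) /
    (grid[inner + 1L] - grid[inner - 1L])
  depsR[inner] <- depsL[inner]
  for (i in which(is_knot)) {
    if (i >= 3L) {
      hb <- grid[i] - grid[i - 1L]
      depsL[i] <- (3 * eps[i] - 4 * eps[i - 1L] + eps[i - 2L]) / (2 * hb)
    } else if (i == 2L) depsL[i] <- (eps[2L] - eps[1L]) / h[1L]
    if (i <= n - 2L) {
      hf <- grid[i + 1L] - grid[i]
      depsR[i] <- (-3 * eps[i] + 4 * eps[i + 1L] - eps[i + 2L]) / (2 * hf)
    } else if (i == n - 1L) depsR[i] <- (eps[n] - eps[n - 1L]) / h[n - 1L]
  }
  depsL[1L] <- depsR[1L]; depsR[n] <- depsL[n]

  if (is.null(eval_times)) eval_times <- seq(t_start, t_end, length.out = 200L)
  E_of <- function(lag) visco$E_R + (visco$E_U - visco$E_R) *
    exp(-lag / visco$tau_r)
  sig <- vapply(eval_times, function(tk) {
    m <- findInterval(tk + 1e-12, grid)
    if (m < 2L) return(0)
    # trapezoid per interval: left endpoint uses the right-sided
    # derivative, right endpoint the left-sided one
    gi <- seq_len(m - 1L)
    Eg <- E_of(tk - grid[seq_len(m)])
    val <- sum(h[gi] / 2 * (Eg[gi] * depsR[gi] + Eg[gi + 1L] * depsL[gi + 1L]))
    # partial interval [g_m, tk] when tk falls between nodes
    if (m < n && tk > grid[m]) {
      hh <- tk - grid[m]
      frac <- hh / (grid[m + 1L] - grid[m])
      deps_tk <- depsR[m] + frac * (depsL[m + 1L] - depsR[m])
      val <- val + hh / 2 * (E_of(hh) * depsR[m] + visco$E_U * deps_tk)
    }
    val
  }, numeric(1))

  response_curve(times = eval_times, values = sig,
                 channel_label = "oracle")
}
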