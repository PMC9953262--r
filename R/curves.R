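#' Single-channel sensor response curve
#'
#' Uniformly sampled time series of one receptor channel's signal.
#'
#' @param times Sample times (s), strictly increasing and uniform to within
#'   1e-9 s.
#' @param values Signal values, finite, same length as `times`.
#' @param sampling_rate Sampling rate (Hz); inferred from `times` when
#'   omitted, and checked for consistency when given.
#' @param channel_label Receptor name (free text, e.g. "PS", "PMMA",
#'   "Tenax").
#' @return An object of class `response_curve` with elements `times`,
#'   `values`, `sampling_rate`, `channel_label`.
#' @export
response_curve <- function(times, values, sampling_rate = NULL,
                           channel_label = "ch1") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) < 2L) stop("need at least two samples")
  dtv <- diff(times)
  if (any(dtv <= 0)) stop("times must be strictly increasing")
  if (max(dtv) - min(dtv) > 1e-9)
    stop("times must be uniformly sampled (1e-9 s tolerance)")
  if (any(!is.finite(values))) stop("values must be finite")
  dt <- stats::median(dtv)
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / dt
  } else if (abs(sampling_rate * dt - 1) > 1e-6) {
    stop("sampling_rate inconsistent with times")
  }
  structure(list(times = times, values = values,
                 sampling_rate = sampling_rate,
                 channel_label = as.character(channel_label)),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("response_curve '%s': %d samples @ %g Hz, t in [%g, %g] s\n",
              x$channel_label, length(x$times), x$sampling_rate,
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Sample the closed-form model into a response curve
#'
#' Convenience wrapper: evaluates [superposition_response()] on a uniform
#' grid.
#'
#' @param params A [sorption_params()] object.
#' @param schedule A [switching_schedule()].
#' @param sampling_rate Hz.
#' @param t_start,t_end Recording window (s); defaults span the schedule
#'   with a 10 s baseline and one half-period of tail.
#' @param channel_label Channel name for the curve.
#' @return A [response_curve()].
#' @export
sample_model_curve <- function(params, schedule, sampling_rate,
                               t_start = NULL, t_end = NULL,
                               channel_label = "model") {
  st <- schedule$switch_times
  if (is.null(t_start)) t_start <- st[1L] - 10
  if (is.null(t_end)) {
    tail_len <- if (isTRUE(schedule$equal_T)) schedule$half_period_T
      else max(diff(st))
    t_end <- st[length(st)] + tail_len
  }
  times <- seq(t_start, t_end, by = 1 / sampling_rate)
  response_curve(times, superposition_response(params, schedule, times),
                 sampling_rate, channel_label)
}
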