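#' Detect the response onset time of a curve
#'
#' Default method `"derivative"`: smooth the signal with a short running
#' mean, take its first difference, estimate the baseline derivative noise
#' from the first second of data, and return the first time at which the
#' derivative exceeds `k` baseline standard deviations for `m` consecutive
#' samples. If `nominal_valve_time` is supplied the search is restricted to
#' a window of +/- 2 s around it. Method `"nominal"` returns the supplied
#' valve time unchanged (rigs and simulators both know it).
#'
#' @param curve A [response_curve()] with at least 1 s of pre-rise baseline.
#' @param method `"derivative"` (default) or `"nominal"`.
#' @param nominal_valve_time Optional valve switch time (s).
#' @param k Threshold in baseline-sd units (default 5).
#' @param m Consecutive super-threshold samples required (default 5).
#' @return Onset time `t0` in seconds.
#' @export
detect_onset <- function(curve, method = c("derivative", "nominal"),
                         nominal_valve_time = NULL, k = 5, m = 5) {
  stopifnot(inherits(curve, "response_curve"))
  method <- match.arg(method)
  if (method == "nominal") {
    if (is.null(nominal_valve_time))
      stop("method 'nominal' needs nominal_valve_time")
    return(nominal_valve_time)
  }
  v <- curve$values
  tt <- curve$times
  rate <- curve$sampling_rate
  # causal running-mean smoothing over ~0.25 s (at least 3 samples);
  # a centered filter would anticipate the rise by half a window
  w <- max(3L, as.integer(round(rate * 0.25)))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- stats::filter(v, rep(1 / w, w), sides = 1L)
  sm[is.na(sm)] <- v[is.na(sm)]
  sm <- as.numeric(sm)
  # slope proxy: lagged difference of the smoothed signal over one window
  # (a single-sample diff at 100 Hz would drown in noise)
  dv <- c(numeric(w), sm[(w + 1L):length(sm)] - sm[1:(length(sm) - w)])

  search <- seq_along(tt)
  if (!is.null(nominal_valve_time)) {
    search <- which(tt >= nominal_valve_time - 2 & tt <= nominal_valve_time + 2)
    if (length(search) < m) stop("search window around nominal valve time too short")
  }
  base_idx <- which(tt < tt[1L] + 1)
  if (length(base_idx) < 5L) stop("need >= 1 s of pre-injection baseline")
  base_sd <- stats::sd(dv[base_idx])
  # floor the threshold for noiseless curves where baseline sd is ~0
  thr <- max(k * base_sd, .Machine$double.eps * 1e3 * max(abs(v)))
  above <- abs(dv[search]) > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= m) return(tt[search[i - m + 1L]])
  }
  stop("no rise detected (derivative never exceeded threshold)")
}

#' Extract the five time-anchored features from one channel
#'
#' Computes `S_i = S(t0 + offset_i) - S(t0)` at the five anchors. The
#' defaults, offsets (2, 10, 120, 122, 130) s, put the first three on the
#' rising curve (the third at the end of a 2 min sampling window) and the
#' last two at 2 s and 10 s into the decay. Anchor values use the nearest
#' recorded sample (no interpolation): at 20-100 Hz the placement error is
#' at most half a sample interval, negligible against the 2 s anchor
#' spacing.
#'
#' @param curve A [response_curve()].
#' @param t0 Onset time (s), e.g. from [detect_onset()].
#' @param offsets Anchor offsets after `t0` (s), strictly increasing.
#' @param baseline `"sample"` (default; the single nearest sample at `t0`)
#'   or `"pre_mean"` (mean of the second preceding `t0`).
#' @return An object of class `feature_vector`: list with `channel_label`,
#'   `t0_used`, `offsets`, `values` (named S1..S5 for the default anchors).
#' @export
extract_features <- function(curve, t0, offsets = c(2, 10, 120, 122, 130),
                             baseline = c("sample", "pre_mean")) {
  stopifnot(inherits(curve, "response_curve"))
  baseline <- match.arg(baseline)
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  tt <- curve$times
  t_max <- tt[length(tt)]
  need <- t0 + max(offsets)
  if (need > t_max + 0.5 / curve$sampling_rate) {
    miss <- offsets[t0 + offsets > t_max + 0.5 / curve$sampling_rate][1L]
    stop(sprintf("curve too short: anchor t0+%g s = %g s beyond last sample %g s",
                 miss, t0 + miss, t_max))
  }
  nearest <- function(x) {
    i <- round((x - tt[1L]) * curve$sampling_rate) + 1
    curve$values[min(max(i, 1), length(tt))]
  }
  base <- if (baseline == "sample") nearest(t0) else {
    idx <- which(tt >= t0 - 1 & tt < t0)
    if (length(idx) < 1L) stop("no samples in the second preceding t0")
    mean(curve$values[idx])
  }
  vals <- vapply(offsets, function(o) nearest(t0 + o) - base, numeric(1))
  names(vals) <- paste0("S", seq_along(offsets))
  structure(list(channel_label = curve$channel_label, t0_used = t0,
                 offsets = offsets, values = vals),
            class = "feature_vector")
}

#' Assemble the study feature matrix from multi-channel measurements
#'
#' One row per measurement, `length(offsets)` features per channel, columns
#' channel-major (`<channel>_S1 ... <channel>_S5` per channel). The onset is
#' shared across a measurement's channels by default (the valve event is
#' common to the array); per-channel detection is available.
#'
#' @param measurements List of measurements; each is a list with elements
#'   `curves` (named list of [response_curve()], same channel set
#'   everywhere), `sample_id`, `group`, `replicate`, and optionally
#'   `valve_time`.
#' @param onset_method `"nominal"` (default; uses each measurement's
#'   `valve_time`) or `"derivative"`.
#' @param offsets Anchor offsets (s), as in [extract_features()].
#' @param shared_t0 Detect one onset per measurement (default TRUE, on the
#'   first channel) rather than per channel.
#' @return A `feature_matrix`: list with `meta` (data.frame sample_id,
#'   group, replicate) and `values` (numeric matrix).
#' @export
assemble_feature_matrix <- function(measurements,
                                    onset_method = c("nominal", "derivative"),
                                    offsets = c(2, 10, 120, 122, 130),
                                    shared_t0 = TRUE) {
  onset_method <- match.arg(onset_method)
  n_off <- length(offsets)
  if (length(measurements) == 0L) {
    return(structure(list(
      meta = data.frame(sample_id = character(), group = character(),
                        replicate = integer()),
      values = matrix(numeric(), nrow = 0L, ncol = 0L)),
      class = "feature_matrix"))
  }
  ch_names <- names(measurements[[1L]]$curves)
  cols <- as.vector(t(outer(ch_names, paste0("S", seq_len(n_off)), paste, sep = "_")))
  vals <- matrix(NA_real_, nrow = length(measurements), ncol = length(cols),
                 dimnames = list(NULL, cols))
  meta <- data.frame(sample_id = character(length(measurements)),
                     group = character(length(measurements)),
                     replicate = integer(length(measurements)))
  for (r in seq_along(measurements)) {
    me <- measurements[[r]]
    if (!identical(names(me$curves), ch_names))
      stop("channel set mismatch at measurement ", r)
    t0_shared <- NULL
    if (shared_t0) {
      t0_shared <- if (onset_method == "nominal") me$valve_time
        else detect_onset(me$curves[[1L]], "derivative",
                          nominal_valve_time = me$valve_time)
      if (is.null(t0_shared)) stop("measurement ", r, " lacks valve_time")
    }
    for (ch in ch_names) {
      t0 <- if (shared_t0) t0_shared
        else if (onset_method == "nominal") me$valve_time
        else detect_onset(me$curves[[ch]], "derivative",
                          nominal_valve_time = me$valve_time)
      fv <- extract_features(me$curves[[ch]], t0, offsets)
      vals[r, paste(ch, names(fv$values), sep = "_")] <- fv$values
    }
    meta$sample_id[r] <- me$sample_id
    meta$group[r] <- me$group
    meta$replicate[r] <- me$replicate
  }
  structure(list(meta = meta, values = vals), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d measurement(s) x %d feature(s)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Replicate-to-replicate relative deviation of features
#'
#' Reproducibility summary: for each sample and feature, the spread
#' `(max - min)` across replicates divided by the absolute mean
#' signal-intensity feature (by default `S3`, the output at the end of the
#' sampling window) of that feature's channel, expressed as a fraction.
#'
#' @param fm A `feature_matrix` with >= 2 replicates per sample.
#' @param intensity_anchor Name of the anchor used as the intensity
#'   denominator (default `"S3"`).
#' @return List with `deviations` (data.frame sample_id, feature, deviation,
#'   flagged), `max_deviation` (maximum over all non-flagged cells), and
#'   `n_flagged` (cells excluded for a zero intensity denominator).
#' @export
replicate_relative_deviation <- function(fm, intensity_anchor = "S3") {
  stopifnot(inherits(fm, "feature_matrix"))
  ids <- unique(fm$meta$sample_id)
  feats <- colnames(fm$values)
  channels <- sub("_S[0-9]+$", "", feats)
  rows <- list()
  for (sid in ids) {
    sel <- fm$meta$sample_id == sid
    if (sum(sel) < 2L) stop("sample ", sid, " has fewer than 2 replicates")
    sub <- fm$values[sel, , drop = FALSE]
    for (j in seq_along(feats)) {
      denom_col <- paste(channels[j], intensity_anchor, sep = "_")
      denom <- abs(mean(sub[, denom_col]))
      spread <- max(sub[, j]) - min(sub[, j])
      flagged <- denom < .Machine$double.eps * 1e3
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, feature = feats[j],
        deviation = if (flagged) NA_real_ else spread / denom,
        flagged = flagged)
    }
  }
  dev <- do.call(rbind, rows)
  ok <- !dev$flagged
  list(deviations = dev,
       max_deviation = if (any(ok)) max(dev$deviation[ok]) else NA_real_,
       n_flagged = sum(dev$flagged))
}
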