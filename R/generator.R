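.VFA_NAMES <- c("acetic", "propionic", "butyric", "valeric", "caproic")

#' Canonical silage sample panels (headspace VFA concentrations)
#'
#' The embedded study fixture: six corn-silage samples from two silo
#' positions -- S1-1..S1-3 (upper) and S2-1..S2-3 (bottom) -- with their
#' mean headspace vapor concentrations in ppm for acetic, propionic,
#' butyric and valeric acid, plus a water blank (all VFAs zero). Caproic
#' acid was below the panel's detection set and is carried as 0. The bottom
#' group (S2) runs roughly 4.2x higher in acetic acid and 1.7x higher in
#' butyric acid than the upper group (S1) -- the contrast the discrimination
#' pipeline must recover.
#'
#' @return data.frame with columns sample_id, group, acetic, propionic,
#'   butyric, valeric, caproic (ppm) and water_activity (1 before
#'   Raoult adjustment).
#' @export
default_panels <- function() {
  data.frame(
    sample_id = c("S1-1", "S1-2", "S1-3", "S2-1", "S2-2", "S2-3", "water"),
    group = c(rep("S1", 3L), rep("S2", 3L), "water"),
    acetic = c(15.5, 31.7, 26.1, 108, 103, 98.8, 0),
    propionic = c(3.72, 5.97, 5.75, 8.89, 7.21, 7.27, 0),
    butyric = c(9.84, 8.78, 9.27, 16.8, 15.2, 15.4, 0),
    valeric = c(0.64, 0.64, 0.74, 2.09, 1.56, 1.66, 0),
    caproic = c(0, 0, 0, 0, 0, 0, 0),
    water_activity = 1,
    stringsAsFactors = FALSE)
}

#' Water mole fraction under ideal Raoult behavior
#'
#' Dissolved acids depress the water vapor pressure in proportion to their
#' mole fractions: the remaining water mole fraction is `1 - sum(solute
#' fractions)`, and the water-channel drive concentration scales with it.
#'
#' @param solute_fractions Numeric vector of solute mole fractions, each
#'   >= 0, summing to < 1.
#' @return Water mole fraction in `[0, 1]`.
#' @export
raoult_water_fraction <- function(solute_fractions) {
  if (any(solute_fractions < 0)) stop("solute fractions must be >= 0")
  s <- sum(solute_fractions)
  if (s >= 1) stop("solute fractions must sum to < 1")
  1 - s
}

#' Default receptor x analyte response models
#'
#' Phenomenological per-channel kinetics for three receptor films --
#' hydrophobic polystyrene ("PS"), hydrophilic PMMA (water-dominated), and
#' the hydrophobic trapping polymer "Tenax" -- against the four panel acids,
#' caproic acid, and water. Values are fixtures chosen to reproduce the
#' qualitative physics, not measured constants: every acid's diffusion time
#' constant exceeds water's (slow desorbers), acetic acid is the slowest,
#' PMMA's water sensitivity dominates its response, and each film carries
#' one stress-relaxation time with a mild viscoelastic overshoot
#' (alpha > 1).
#'
#' @return data.frame with columns receptor, analyte, sensitivity (signal
#'   units per ppm), alpha, tau_s (s), tau_r (s), tau_s_desorb (s; equals
#'   tau_s until [dissociation_delay()] is applied).
#' @export
default_receptor_models <- function() {
  g <- expand.grid(analyte = c(.VFA_NAMES, "water"),
                   receptor = c("PS", "PMMA", "Tenax"),
                   stringsAsFactors = FALSE)[, c(2, 1)]
  sens <- c(
    PS    = c(acetic = 4e-3, propionic = 6e-3, butyric = 8e-3,
              valeric = 2e-2, caproic = 4e-2, water = 1e-5),
    PMMA  = c(acetic = 2e-3, propionic = 2.5e-3, butyric = 3e-3,
              valeric = 8e-3, caproic = 1.5e-2, water = 1e-4),
    Tenax = c(acetic = 3e-3, propionic = 5e-3, butyric = 1e-2,
              valeric = 3e-2, caproic = 6e-2, water = 8e-6))
  tau_s <- c(acetic = 40, propionic = 10, butyric = 18, valeric = 25,
             caproic = 30, water = 3)
  # mild per-receptor modulation of the shared analyte kinetics
  tau_mod <- c(PS = 1.0, PMMA = 1.2, Tenax = 0.8)
  tau_r <- c(PS = 80, PMMA = 50, Tenax = 100)
  alpha <- c(PS = 1.2, PMMA = 1.1, Tenax = 1.3)
  g$sensitivity <- sens[paste(g$receptor, g$analyte, sep = ".")]
  g$alpha <- alpha[g$receptor]
  g$tau_s <- tau_s[g$analyte] * tau_mod[g$receptor]
  g$tau_r <- tau_r[g$receptor]
  g$tau_s_desorb <- g$tau_s
  rownames(g) <- NULL
  g
}

#' Generator configuration
#'
#' @param protocol `"silage"` (120 s sampling then 480 s purge, 100 Hz) or
#'   `"pure_vfa"` (10 s on/off, 4 cycles, 20 Hz).
#' @param noise_sd Gaussian per-sample noise sd as a fraction of each
#'   channel's clean signal maximum. Default 0.001, calibrated so the
#'   feature-level replicate deviation stays under the 1 percent
#'   reproducibility bound of the emulated study (see the methods
#'   vignette).
#' @param drift_sd Per-measurement linear drift: each channel draws a slope
#'   from `N(0, (drift_sd * channel max)^2)` per second. Small but nonzero
#'   by default; drift is what the second principal component picks up.
#' @param n_replicates Replicates per sample panel (default 3).
#' @param baseline_s Recorded baseline before the valve opens (s).
#' @param water_ppm Headspace water vapor concentration for a pure-water
#'   sample (ppm); ~3 percent v/v, saturation near 25-30 C.
#' @param henry_ppm_to_molefrac Per-acid constants converting headspace ppm
#'   to an aqueous solute mole fraction for the Raoult adjustment
#'   (placeholder config, not claims).
#' @param dissociation_delay_factor Desorption delay factor applied to acid
#'   analytes in the presence of water (>= 1; see [dissociation_delay()]).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(protocol = c("silage", "pure_vfa"),
                             noise_sd = 0.001, drift_sd = 5e-6,
                             n_replicates = 3L, baseline_s = 10,
                             water_ppm = 30000,
                             henry_ppm_to_molefrac = c(
                               acetic = 2.5e-4, propionic = 3e-4,
                               butyric = 4e-4, valeric = 5e-4,
                               caproic = 6e-4),
                             dissociation_delay_factor = 3,
                             seed = 1L) {
  protocol <- match.arg(protocol)
  if (noise_sd < 0 || drift_sd < 0) stop("noise/drift must be >= 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (dissociation_delay_factor < 1) stop("delay factor must be >= 1")
  proto <- if (protocol == "silage") {
    list(inject_s = 120, purge_s = 480, rate_hz = 100)
  } else {
    list(half_period_s = 10, n_cycles = 4L, rate_hz = 20)
  }
  structure(c(list(protocol = protocol, noise_sd = noise_sd,
                   drift_sd = drift_sd,
                   n_replicates = as.integer(n_replicates),
                   baseline_s = baseline_s, water_ppm = water_ppm,
                   henry_ppm_to_molefrac = henry_ppm_to_molefrac,
                   dissociation_delay_factor = dissociation_delay_factor,
                   seed = as.integer(seed)),
              proto),
            class = "generator_config")
}

#' Schedule implied by a generator protocol
#'
#' @param config A [generator_config()].
#' @return A [switching_schedule()] starting at `baseline_s`.
#' @export
protocol_schedule <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$protocol == "silage") {
    switching_schedule(switch_times = config$baseline_s +
                         c(0, config$inject_s))
  } else {
    switching_schedule(t0 = config$baseline_s,
                       half_period_T = config$half_period_s,
                       n_cycles = config$n_cycles)
  }
}

#' Apply a dissociation-driven desorption delay to acid analytes
#'
#' Phenomenological stand-in for the acid-dissociation equilibrium in a
#' hydrated receptor layer: in the presence of water, dissociated acid must
#' re-associate before it can desorb, delaying the decay. Implemented by
#' multiplying the desorption-phase diffusion time constant of every acid
#' analyte by `delay_factor` when `water_present`; rise kinetics are
#' untouched, so the asymmetry appears only on the decay and only with
#' water.
#'
#' @param models A model table as from [default_receptor_models()].
#' @param water_present Logical; factor 1 behavior when FALSE.
#' @param delay_factor >= 1; 1 is a no-op.
#' @return The adjusted model table.
#' @export
dissociation_delay <- function(models, water_present, delay_factor) {
  if (delay_factor < 1) stop("delay_factor must be >= 1")
  out <- models
  out$tau_s_desorb <- out$tau_s
  if (isTRUE(water_present)) {
    acid <- out$analyte %in% .VFA_NAMES
    out$tau_s_desorb[acid] <- out$tau_s[acid] * delay_factor
  }
  out
}

# run fn with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate one multi-channel measurement
#'
#' Per channel, the clean signal is the sum over analytes of
#' `sensitivity * drive_ppm` scaled unit responses
#' ([superposition_response()] with the analyte's kinetics and the
#' protocol schedule), the water drive being suppressed by
#' [raoult_water_fraction()] of the panel's dissolved acids. Gaussian
#' noise (sd = `noise_sd` x channel max) and a per-channel random linear
#' drift are then added. Mixtures are additive: no competitive sorption.
#'
#' @param panel One row of a panel table (see [default_panels()]).
#' @param models Model table covering every panel analyte plus water for
#'   every receptor.
#' @param config A [generator_config()].
#' @param seed Seed for this measurement's noise; default derives from
#'   `config$seed`.
#' @return Named list of [response_curve()] (one per receptor) with
#'   attributes `valve_time` and `clean` (the noiseless channel matrix).
#' @export
simulate_measurement <- function(panel, models, config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  sched <- protocol_schedule(config)
  receptors <- unique(models$receptor)
  analytes <- c(.VFA_NAMES, "water")
  need <- analytes[c(unlist(panel[.VFA_NAMES]) > 0, TRUE)]
  for (r in receptors) {
    have <- models$analyte[models$receptor == r]
    if (!all(need %in% have))
      stop("missing (", r, ", ", paste(setdiff(need, have), collapse = ","),
           ") model")
  }
  # Raoult: dissolved acids depress the water drive
  solute <- unlist(panel[.VFA_NAMES]) *
    config$henry_ppm_to_molefrac[.VFA_NAMES]
  wfrac <- raoult_water_fraction(solute) * panel$water_activity
  drives <- c(unlist(panel[.VFA_NAMES]), water = config$water_ppm * wfrac)

  water_present <- drives[["water"]] > 0
  models <- dissociation_delay(models, water_present,
                               config$dissociation_delay_factor)

  t_end <- max(sched$switch_times) +
    if (config$protocol == "silage") config$purge_s else config$half_period_s
  times <- seq(0, t_end, by = 1 / config$rate_hz)

  clean <- matrix(0, length(times), length(receptors),
                  dimnames = list(NULL, receptors))
  for (r in receptors) {
    mr <- models[models$receptor == r, , drop = FALSE]
    for (a in analytes) {
      drv <- drives[[a]]
      if (drv <= 0) next
      row <- mr[mr$analyte == a, , drop = FALSE]
      amp <- row$sensitivity * drv
      if (amp == 0) next
      p <- sorption_params(1, row$alpha, row$tau_s, row$tau_r,
                           t0 = sched$t0, sign = 1)
      desorb <- if (row$tau_s_desorb != row$tau_s) row$tau_s_desorb else NULL
      clean[, r] <- clean[, r] +
        amp * superposition_response(p, sched, times, tau_s_desorb = desorb)
    }
  }
  out <- .with_seed(seed, function() {
    lapply(receptors, function(r) {
      mx <- max(abs(clean[, r]))
      scale_ref <- if (mx > 0) mx else 1
      noise <- stats::rnorm(length(times), 0, config$noise_sd * scale_ref)
      slope <- stats::rnorm(1L, 0, config$drift_sd * scale_ref)
      response_curve(times, clean[, r] + noise + slope * times,
                     config$rate_hz, r)
    })
  })
  names(out) <- receptors
  attr(out, "valve_time") <- sched$t0
  attr(out, "clean") <- clean
  out
}

#' Generate the full synthetic study bundle
#'
#' Default design mirrors the emulated study: 6 silage panels x 3
#' replicates plus 3 water-blank replicates = 21 measurements, each with 3
#' receptor channels under the silage protocol (2 min sampling, 8 min
#' purge, 100 Hz). Ground-truth kinetic parameters travel with the bundle
#' for parameter-recovery tests. The bundle is a pure function of
#' `(config, panels, models)` -- the same seed reproduces it bit for bit.
#'
#' @param config A [generator_config()].
#' @param panels Panel table; defaults to [default_panels()].
#' @param models Model table; defaults to [default_receptor_models()].
#' @return List with `measurements` (each: `curves`, `sample_id`, `group`,
#'   `replicate`, `valve_time`), `truth` (the model table after
#'   dissociation adjustment plus per-measurement drives), `panels`,
#'   `schedule`, `config`.
#' @export
generate_dataset <- function(config = generator_config(),
                             panels = default_panels(),
                             models = default_receptor_models()) {
  sched <- protocol_schedule(config)
  measurements <- list()
  idx <- 0L
  for (i in seq_len(nrow(panels))) {
    for (rep_i in seq_len(config$n_replicates)) {
      idx <- idx + 1L
      # sub-seed per measurement, kept well under 2^31
      sub_seed <- (config$seed * 1000L + idx) %% .Machine$integer.max
      curves <- simulate_measurement(panels[i, , drop = FALSE], models,
                                     config, seed = sub_seed)
      measurements[[idx]] <- list(
        curves = curves[seq_along(curves)],
        sample_id = panels$sample_id[i],
        group = panels$group[i],
        replicate = rep_i,
        valve_time = attr(curves, "valve_time"))
    }
  }
  truth <- dissociation_delay(models, TRUE, config$dissociation_delay_factor)
  list(measurements = measurements, truth = truth, panels = panels,
       schedule = sched, config = config)
}

#' Group-mean headspace concentration ratios
#'
#' For each VFA, the arithmetic mean concentration over the S2-group panels
#' divided by the mean over the S1-group panels -- the study's summary of
#' how much richer the spoiled (bottom) silage runs in each acid.
#'
#' @param panels Panel table with a `group` column containing "S1" and
#'   "S2"; defaults to [default_panels()] (water blanks are ignored).
#' @return data.frame with columns vfa, mean_s1, mean_s2, ratio (full
#'   precision) and ratio_2sf (2 significant figures); ratio is NA with a
#'   `flagged` mark when the S1 mean is zero.
#' @export
group_ratio_summary <- function(panels = default_panels()) {
  s1 <- panels[panels$group == "S1", , drop = FALSE]
  s2 <- panels[panels$group == "S2", , drop = FALSE]
  if (nrow(s1) == 0L || nrow(s2) == 0L) stop("both groups must be non-empty")
  vfas <- intersect(.VFA_NAMES, colnames(panels))
  out <- do.call(rbind, lapply(vfas, function(v) {
    m1 <- mean(s1[[v]]); m2 <- mean(s2[[v]])
    zero <- abs(m1) < .Machine$double.eps
    data.frame(vfa = v, mean_s1 = m1, mean_s2 = m2,
               ratio = if (zero) NA_real_ else m2 / m1,
               ratio_2sf = if (zero) NA_real_ else signif(m2 / m1, 2L),
               flagged = zero)
  }))
  rownames(out) <- NULL
  out
}
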