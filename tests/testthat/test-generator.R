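test_that("default_panels carries the canonical concentration table", {
  p <- default_panels()
  expect_identical(nrow(p), 7L)  # 6 silage + 1 water blank
  expect_equal(p$acetic[p$sample_id == "S2-1"], 108)
  expect_equal(p$butyric[p$sample_id == "S1-1"], 9.84)
  blank <- p[p$group == "water", ]
  expect_true(all(blank[, c("acetic", "propionic", "butyric",
                            "valeric", "caproic")] == 0))
})

test_that("group_ratio_summary reproduces the printed group contrasts", {
  g <- group_ratio_summary()
  expect_equal(g$ratio_2sf[g$vfa == "acetic"], 4.2)
  expect_equal(g$ratio_2sf[g$vfa == "butyric"], 1.7)
  # propionic ratio is plain arithmetic over the table column
  expect_equal(g$ratio[g$vfa == "propionic"],
               mean(c(8.89, 7.21, 7.27)) / mean(c(3.72, 5.97, 5.75)),
               tolerance = 1e-12)
  # zero-denominator flagging
  p <- default_panels()
  p$caproic[p$group == "S2"] <- 1
  g2 <- group_ratio_summary(p)
  expect_true(g2$flagged[g2$vfa == "caproic"])
  expect_true(is.na(g2$ratio[g2$vfa == "caproic"]))
})

test_that("raoult_water_fraction: bounds, monotonicity, rejection", {
  expect_identical(raoult_water_fraction(numeric(0)), 1)
  expect_equal(raoult_water_fraction(0.1), 0.9)
  expect_equal(raoult_water_fraction(c(0.1, 0.05)), 0.85)
  # monotone decreasing in each solute fraction
  expect_lt(raoult_water_fraction(c(0.2, 0.1)),
            raoult_water_fraction(c(0.1, 0.1)))
  expect_error(raoult_water_fraction(c(0.6, 0.5)), "< 1")
  expect_error(raoult_water_fraction(-0.1), ">= 0")
})

test_that("dissociation_delay adjusts acid desorption only with water", {
  m <- default_receptor_models()
  expect_identical(dissociation_delay(m, TRUE, 1)$tau_s_desorb, m$tau_s)
  m3 <- dissociation_delay(m, TRUE, 3)
  acid <- m3$analyte != "water"
  expect_equal(m3$tau_s_desorb[acid], 3 * m3$tau_s[acid])
  expect_equal(m3$tau_s_desorb[!acid], m3$tau_s[!acid])
  # no water, no delay
  expect_identical(dissociation_delay(m, FALSE, 3)$tau_s_desorb, m$tau_s)
  expect_error(dissociation_delay(m, TRUE, 0.5), ">= 1")
})

test_that("desorption delay slows the decay only in the presence of water", {
  cfg <- fast_config()
  models <- default_receptor_models()
  panel <- default_panels()[1, ]
  sched <- protocol_schedule(cfg)
  purge_start <- sched$switch_times[2]
  probe <- function(delay, water) {
    cfg2 <- generator_config(protocol = "pure_vfa", seed = 1, noise_sd = 0,
                             drift_sd = 0, dissociation_delay_factor = delay,
                             water_ppm = if (water) 30000 else 0)
    m <- simulate_measurement(panel, models, cfg2)
    clean <- attr(m, "clean")
    i <- which.min(abs(m$PS$times - (purge_start + 5)))
    clean[i, "PS"]
  }
  # slower decay => larger residual signal at fixed offset after purge start
  expect_gt(probe(3, water = TRUE), probe(1, water = TRUE))
  # asymmetry machinery inert without water
  expect_equal(probe(3, water = FALSE), probe(1, water = FALSE))
})

test_that("simulate_measurement: zero sensitivities, determinism, model cover", {
  cfg <- fast_config(noise_sd = 0, drift_sd = 0)
  models <- default_receptor_models()
  panel <- default_panels()[1, ]
  z <- models; z$sensitivity <- 0
  mz <- simulate_measurement(panel, z, cfg)
  expect_true(all(vapply(mz, function(cu) max(abs(cu$values)), numeric(1)) == 0))
  cfgN <- fast_config(seed = 99)
  m1 <- simulate_measurement(panel, models, cfgN)
  m2 <- simulate_measurement(panel, models, cfgN)
  expect_identical(m1$PS$values, m2$PS$values)
  expect_identical(m1$Tenax$values, m2$Tenax$values)
  missing <- models[!(models$receptor == "PS" & models$analyte == "water"), ]
  expect_error(simulate_measurement(panel, missing, cfg), "missing")
})

test_that("hydrophilic channel is water dominated; hydrophobic decay separates groups", {
  cfg <- fast_config(noise_sd = 0, drift_sd = 0)
  models <- default_receptor_models()
  panels <- default_panels()
  # water term on PMMA >= 80% of its amplitude
  m_full <- simulate_measurement(panels[1, ], models, cfg)
  dry <- panels[1, ]
  cfg_dry <- generator_config("pure_vfa", noise_sd = 0, drift_sd = 0,
                              water_ppm = 0, seed = 1)
  m_dry <- simulate_measurement(dry, models, cfg_dry)
  water_share <- 1 - max(abs(m_dry$PMMA$values)) / max(abs(m_full$PMMA$values))
  expect_gte(water_share, 0.8)
  # S2-like panels give larger hydrophobic decay features than S1-like,
  # in every replicate (silage protocol anchors)
  cfg_s <- generator_config("silage", seed = 5)
  for (rep_i in 1:3) {
    f <- function(row) {
      m <- simulate_measurement(panels[row, ], default_receptor_models(),
                                cfg_s, seed = 1000 + rep_i + 7 * row)
      extract_features(m$PS, attr(m, "valve_time"))$values[c("S4", "S5")]
    }
    expect_true(all(f(4) > f(1)))  # S2-1 vs S1-1
  }
})

test_that("generate_dataset: design shape, reproducibility, truth round-trip", {
  cfg <- fast_config(seed = 3)
  ds <- generate_dataset(cfg)
  # 6 silage panels x 3 replicates + 3 water blanks
  expect_length(ds$measurements, 21L)
  expect_identical(
    table(vapply(ds$measurements, `[[`, character(1), "group")),
    table(factor(rep(c("S1", "S2", "water"), c(9, 9, 3)))))
  expect_length(ds$measurements[[1]]$curves, 3L)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$measurements[[7]]$curves$PMMA$values,
                   ds2$measurements[[7]]$curves$PMMA$values)
  # truth parameters round-trip through fit_response: fit the noiseless
  # acetic-only PS response and recover the configured tau_s
  models <- default_receptor_models()
  row <- models[models$receptor == "PS" & models$analyte == "acetic", ]
  sched <- protocol_schedule(cfg)
  p <- sorption_params(1, row$alpha, row$tau_s, row$tau_r, sched$t0)
  cu <- sample_model_curve(p, sched, cfg$rate_hz,
                           t_start = 0, t_end = 100, channel_label = "PS")
  fr <- fit_response(cu, sched)
  expect_lt(abs(fr$estimates$tau_s - row$tau_s) / row$tau_s, 0.01)
})
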