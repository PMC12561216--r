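test_that("settings validate their ranges", {
  expect_error(duplicator_settings(cardiac_output_target = -1))
  expect_error(duplicator_settings(systolic_fraction = 100))
  expect_error(duplicator_settings(closing_volume = -2))
  s <- duplicator_settings()
  expect_equal(s$cardiac_output_target, 5.0)
  expect_equal(s$heart_rate, 70)
  expect_equal(s$map_target, 20)
  expect_equal(s$systolic_fraction, 35)
  # ISO normotensive pulmonary ranges
  expect_true(s$pa_end_diastolic >= 8 && s$pa_end_diastolic <= 15)
  expect_true(s$peak_systolic_rv >= 18 && s$peak_systolic_rv <= 35)
})

test_that("the waveform generator is deterministic and hits its targets", {
  s <- duplicator_settings(noise_sd_pressure = 0.3, noise_sd_flow = 3,
                           n_cycles = 2L, seed = 11L)
  w1 <- generate_waveform(s)
  w2 <- generate_waveform(s)
  expect_identical(w1$flow, w2$flow)           # bit-for-bit reproducible
  expect_identical(w1$p_vent, w2$p_vent)
  # zero-noise round trip within 1%
  met <- analyze_waveform(generate_waveform(duplicator_settings()), 70,
                          n_cycles = 10)
  expect_equal(mean(met$cardiac_output), 5.0, tolerance = 0.05)
  expect_equal(mean(met$map), 20, tolerance = 0.2)
  expect_equal(mean(met$tpg), 2.0, tolerance = 0.02)
  expect_equal(mean(met$systolic_fraction), 35, tolerance = 0.35)
  rf_target <- (3 + 2) / (5 / 70 * 1000 + 5) * 100
  expect_equal(mean(met$rf), rf_target, tolerance = 0.02 * rf_target)
  # infeasible combinations rejected
  expect_error(generate_waveform(duplicator_settings(closing_duration = 0.6)),
               "infeasible")
})

test_that("packaged group specifications carry the reference summary values", {
  gs <- group_specs()
  expect_named(gs, paste0("G", 0:6))
  expect_equal(gs$G0$rf_mean, 18.54)
  expect_equal(gs$G0$rf_sd, 8.05)
  expect_equal(gs$G6$rf_mean, 8.22)
  expect_equal(gs$G6$rf_sd, 1.27)
  expect_equal(gs$G6$tpg_mean, 3.06)
  rf <- vapply(gs, `[[`, numeric(1), "rf_mean")
  expect_true(all(diff(rf) < 0))   # monotone decrease G0 -> G6
})

test_that("cohorts draw truncated-normal per-cycle values reproducibly", {
  sp <- group_specs()$G6
  c1 <- generate_cohort(sp, seed = 5, waveforms = FALSE)
  c2 <- generate_cohort(sp, seed = 5, waveforms = FALSE)
  expect_identical(c1$draws, c2$draws)
  expect_equal(nrow(c1$draws), 30L)          # 3 valves x 10 cycles
  expect_true(all(c1$draws$rf >= 0))
  # closing:leakage split at the configured ratio
  expect_equal(c1$draws$closing_volume /
                 (c1$draws$closing_volume + c1$draws$leakage_volume),
               rep(0.6, 30), tolerance = 1e-12)
  # zero-SD spec: all cycles identical
  sp0 <- group_spec("flat", rf_mean = 10, rf_sd = 0, tpg_mean = 2,
                    tpg_sd = 0)
  c0 <- generate_cohort(sp0, seed = 1, waveforms = FALSE)
  expect_equal(var(c0$draws$rf), 0)
  # law of large numbers at n = 1e4 (draw level)
  spN <- group_spec("big", rf_mean = 8.22, rf_sd = 1.27, tpg_mean = 3.06,
                    tpg_sd = 1.00, n_valves = 1000L, n_cycles = 10L)
  cN <- generate_cohort(spN, seed = 2, waveforms = FALSE)
  expect_equal(mean(cN$draws$rf), 8.22, tolerance = 0.05)
  expect_equal(sd(cN$draws$rf), 1.27, tolerance = 0.05)
})

test_that("the analyzer recovers the drawn per-cycle RF from cohort waveforms", {
  suppressWarnings({
    coh <- generate_cohort(group_specs()$G6, seed = 3,
                           settings = duplicator_settings(sampling_rate = 500))
  })
  met <- do.call(rbind, lapply(coh$waveforms, function(w)
    analyze_waveform(w, 70, n_cycles = 10)))
  expect_equal(nrow(met), 30L)
  expect_equal(mean(met$rf), mean(coh$draws$rf), tolerance = 0.1)
  expect_equal(sd(met$rf), sd(coh$draws$rf), tolerance = 0.1)
  expect_equal(mean(met$tpg), mean(coh$draws$tpg), tolerance = 0.03)
})
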