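# small synthetic cycle builders used by several blocks
make_cycle <- function(t, p_vent, p_art, flow, fs = 1 / (t[2] - t[1])) {
  structure(data.frame(time = t, p_vent = p_vent, p_art = p_art, flow = flow),
            period = t[length(t)] - t[1] + (t[2] - t[1]),
            sampling_rate = fs, density = 1.005, class = "data.frame")
}

test_that("cycle segmentation is phase-aligned and returns whole periods", {
  wf <- generate_waveform(duplicator_settings(n_cycles = 12))
  wf10 <- pulse_waveform(wf$time[wf$time < 10], wf$p_vent[wf$time < 10],
                         wf$p_art[wf$time < 10], wf$flow[wf$time < 10])
  cyc <- segment_cycles(wf10, 70)
  expect_length(cyc, 11L)              # floor(10 * 70 / 60)
  expect_length(segment_cycles(wf10, 70, n_cycles = 10), 10L)
  n_per <- round(1000 * 60 / 70)
  expect_true(all(vapply(cyc, nrow, integer(1)) == n_per))
  # exactly one period -> one window
  one <- pulse_waveform(wf$time[1:n_per], wf$p_vent[1:n_per],
                        wf$p_art[1:n_per], wf$flow[1:n_per])
  expect_length(segment_cycles(one, 70), 1L)
  # constant zero flow: degenerate alignment with a warning
  flat <- pulse_waveform(wf$time[1:n_per], wf$p_vent[1:n_per],
                         wf$p_art[1:n_per], rep(0, n_per))
  expect_warning(segment_cycles(flat, 70), "no forward flow")
  expect_error(segment_cycles(one[1:100, ], 70))
})

test_that("the positive differential pressure period is the longest positive run", {
  t <- seq(0, 1, by = 0.001)
  # constant positive gradient: the whole cycle
  c1 <- make_cycle(t, 10, 5, 0 * t)
  expect_equal(unname(positive_pressure_period(c1)), c(0, 1))
  # sinusoidal gradient positive on the first half
  c2 <- make_cycle(t, 5 + sin(2 * pi * t), 5, 0 * t)
  pdp <- positive_pressure_period(c2)
  expect_equal(unname(pdp), c(0, 0.5), tolerance = 0.0011)
  # two positive runs: T/4 then T/3 -> the longer one wins (brute-force
  # run-length construction)
  dp <- numeric(length(t))
  dp[t >= 0.05 & t < 0.30] <- 1          # length 0.25
  dp[t >= 0.50 & t < 0.8333] <- 1        # length 1/3
  c3 <- make_cycle(t, 5 + dp, 5, 0 * t)
  pdp3 <- positive_pressure_period(c3)
  expect_equal(unname(pdp3), c(0.4995, 0.833), tolerance = 0.002)
  expect_error(positive_pressure_period(make_cycle(t, 1, 5, 0 * t)))
})

test_that("TPG is the time-averaged gradient over the PDP", {
  t <- seq(0, 1, by = 0.001)
  expect_equal(tpg(make_cycle(t, 7, 5, 0 * t)), 2, tolerance = 1e-9)
  # half-sine gradient with peak 10 over the full PDP: mean = 20/pi
  c2 <- make_cycle(t, 5 + 10 * pmax(sin(pi * t), 0) *
                     (t <= 1), 5, 0 * t)
  expect_equal(tpg(c2), 20 / pi, tolerance = 1e-3)
  # generator round trip at the reference G0 magnitude
  wf <- generate_waveform(duplicator_settings(tpg_target = 1.49))
  met <- analyze_waveform(wf, 70, n_cycles = 5)
  expect_equal(mean(met$tpg), 1.49, tolerance = 0.01)
})

test_that("qvRMS matches analytic root-mean-square values", {
  t <- seq(0, 1, by = 0.001)
  c1 <- make_cycle(t, 7, 5, rep(100, length(t)))
  expect_equal(qv_rms(c1), 100, tolerance = 1e-9)
  # half-sine of peak Q over the PDP: RMS = Q / sqrt(2)
  c2 <- make_cycle(t, 7, 5, 300 * sin(pi * t))
  expect_equal(qv_rms(c2), 300 / sqrt(2), tolerance = 1e-3)
  expect_equal(qv_rms(make_cycle(t, 7, 5, 0 * t)), 0)
})

test_that("EOA follows the Gorlin-type relation with its algebraic identities", {
  expect_equal(eoa(51.6, 1.005, 1.005), 1.0)
  expect_equal(eoa(200, 4, 1.005), 1.943, tolerance = 1e-3)
  q <- 173; g <- 2.7
  expect_equal(eoa(2 * q, g), 2 * eoa(q, g))
  expect_equal(eoa(q, 4 * g), eoa(q, g) / 2, tolerance = 1e-12)
  expect_error(eoa(100, 0), "gradient")
  expect_error(eoa(100, -2), "gradient")
})

test_that("flow volumes split into forward, closing and leakage", {
  t <- seq(0, 1, by = 0.0005)
  # pure forward half-sine: all volume forward
  q1 <- ifelse(t < 0.35, 400 * sin(pi * t / 0.35), 0)
  v1 <- flow_volumes(make_cycle(t, 7, 5, q1))
  expect_equal(unname(v1["forward"]), 400 * 2 * 0.35 / pi, tolerance = 1e-3)
  expect_equal(unname(v1["closing"]), 0)
  expect_equal(unname(v1["leakage"]), 0)
  # forward 70 mL + triangular backflow spike of 5 mL (analytic area)
  tri <- function(t, t0, dur, peak) {
    x <- (t - t0) / dur
    ifelse(x >= 0 & x < 1, -peak * (1 - abs(2 * x - 1)), 0)
  }
  q2 <- 70 * pi / (2 * 0.35) * ifelse(t < 0.35, sin(pi * t / 0.35), 0) +
    tri(t, 0.36, 0.06, 2 * 5 / 0.06)
  v2 <- flow_volumes(make_cycle(t, 7, 5, q2))
  expect_equal(unname(v2["forward"]), 70, tolerance = 0.01)
  expect_equal(unname(v2["closing"]), 5, tolerance = 0.05)
  expect_equal(unname(v2["leakage"]), 0, tolerance = 0.05)
  # plus a constant leak totaling 3 mL -> RF = 8/70 * 100
  leak_rate <- 3 / (1 - 0.44)
  q3 <- q2 - ifelse(t >= 0.44, leak_rate, 0)
  cyc3 <- make_cycle(t, 7, 5, q3)
  v3 <- flow_volumes(cyc3)
  expect_equal(unname(v3["closing"]), 5, tolerance = 0.1)
  expect_equal(unname(v3["leakage"]), 3, tolerance = 0.1)
  rf <- (v3["closing"] + v3["leakage"]) / v3["forward"] * 100
  expect_equal(unname(rf), 8 / 70 * 100, tolerance = 0.2)
  # degenerate all-zero flow
  expect_equal(unname(flow_volumes(make_cycle(t, 7, 5, 0 * t))), c(0, 0, 0))
})

test_that("volume conservation holds: forward - regurgitant = net integral", {
  set.seed(11)
  for (rep in 1:5) {
    s <- duplicator_settings(closing_volume = runif(1, 0, 8),
                             leakage_volume = runif(1, 0, 5),
                             n_cycles = 2L)
    wf <- generate_waveform(s)
    cyc <- segment_cycles(wf, 70)[[1]]
    v <- flow_volumes(cyc)
    net <- pracma::trapz(cyc$time, cyc$flow)
    expect_equal(unname(v["forward"] - v["closing"] - v["leakage"]), net,
                 tolerance = 0.05)
  }
})

test_that("cycle metrics recover the generator targets", {
  wf <- generate_waveform(duplicator_settings())
  met <- analyze_waveform(wf, 70, n_cycles = 10)
  expect_s3_class(met, "cycle_metrics")
  expect_equal(mean(met$cardiac_output), 5.0, tolerance = 0.01)
  expect_equal(mean(met$map), 20, tolerance = 0.01 * 20)
  expect_equal(mean(met$systolic_fraction), 35, tolerance = 0.35)
  expect_true(all(met$t1 < met$t2))
  expect_equal(met$regurgitant_volume, met$closing_volume +
                 met$leakage_volume)
  # zero-regurgitation fixture
  met0 <- analyze_waveform(
    generate_waveform(duplicator_settings(closing_volume = 0,
                                          leakage_volume = 0)),
    70, n_cycles = 5)
  expect_equal(mean(met0$rf), 0)
})

test_that("RF is invariant under time-axis rescaling", {
  wf <- generate_waveform(duplicator_settings(n_cycles = 3))
  met <- analyze_waveform(wf, 70, n_cycles = 3)
  # stretch time by 2 (volumes scale identically, RF unchanged)
  wf2 <- pulse_waveform(wf$time * 2, wf$p_vent, wf$p_art, wf$flow)
  met2 <- analyze_waveform(wf2, 35, n_cycles = 3)
  expect_equal(mean(met2$rf), mean(met$rf), tolerance = 0.01)
})

test_that("group aggregation reports mean and sample SD", {
  m <- data.frame(rf = c(8, 9, 10), tpg = c(1, 2, 3))
  class(m) <- c("cycle_metrics", "data.frame")
  g <- aggregate_group(m, "demo")
  expect_equal(g$stats$mean[g$stats$metric == "rf"], 9)
  expect_equal(g$stats$sd[g$stats$metric == "rf"], 1)
  expect_equal(g$n, 3L)
  g1 <- aggregate_group(m[1, ], "single")
  expect_true(g1$n1_flag)
  expect_equal(g1$stats$sd, c(0, 0))
})

test_that("one-way ANOVA matches the summary-statistics oracle", {
  # identical groups: F = 0, p = 1
  a <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # clear separation: p below any conventional threshold
  set.seed(4)
  b <- one_way_anova(list(rnorm(5, 0, 1e-3), rnorm(5, 1, 1e-3)))
  expect_lt(b$p, 1e-10)
  # textbook fixture vs summary-statistic identity
  set.seed(9)
  groups <- list(rnorm(12, 5, 2), rnorm(9, 6, 2), rnorm(15, 4.5, 2))
  full <- one_way_anova(groups)
  summ <- anova_from_summary(vapply(groups, mean, numeric(1)),
                             vapply(groups, sd, numeric(1)),
                             lengths(groups))
  expect_equal(full$F, summ$F, tolerance = 1e-10)
  expect_equal(full$p, summ$p, tolerance = 1e-10)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))))
  expect_error(one_way_anova(list(1, c(1, 2))))
})

test_that("the variance F test reports the larger/smaller ratio two-sided", {
  x <- c(1, 2, 3, 4)
  expect_equal(variance_f_test(x, x)$F, 1)
  set.seed(21)
  a <- rnorm(30, 18.54, 8.05)
  b <- rnorm(30, 8.22, 1.27)
  ft <- variance_f_test(a, b)
  expect_gt(ft$F, 1)
  expect_lt(ft$p, 1e-4)
  expect_equal(ft$F, variance_f_test(b, a)$F)  # order invariant
  # cross-check against the base var.test p-value
  expect_equal(ft$p, var.test(a, b)$p.value)
  expect_error(variance_f_test(c(1, 1), c(2, 2)))
})

test_that("waveform CSV round-trips bit-exactly through the documented layout", {
  wf <- generate_waveform(duplicator_settings(n_cycles = 1L))
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, f)
  hdr <- readLines(f, n = 1)
  expect_equal(hdr, "time_s,p_vent_mmHg,p_art_mmHg,q_mL_s")
  back <- read_waveform_csv(f)
  expect_equal(back$flow, wf$flow, tolerance = 1e-12)
  expect_equal(back$p_art, wf$p_art, tolerance = 1e-12)
  unlink(f)
})
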