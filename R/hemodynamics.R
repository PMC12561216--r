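#' Pulse-duplicator waveform container
#'
#' A uniformly sampled time series of ventricular pressure, arterial
#' pressure and transvalvular flow, as exported by a pulse-duplicator
#' system. Positive flow is forward through the valve.
#'
#' @param time Time in s, strictly increasing with constant step.
#' @param p_vent Ventricular pressure, mmHg.
#' @param p_art Arterial pressure, mmHg.
#' @param flow Transvalvular flow, mL/s.
#' @param density Test-fluid density, g/cm^3 (ISO standardized saline
#'   value 1.005 by default).
#' @return A `pulse_waveform` (data frame with attributes
#'   `sampling_rate` and `density`).
#' @export
pulse_waveform <- function(time, p_vent, p_art, flow, density = 1.005) {
  n <- length(time)
  stopifnot(n >= 2L, length(p_vent) == n, length(p_art) == n,
            length(flow) == n)
  if (density <= 0) stop("`density` must be positive")
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * mean(dt))
    stop("`time` must be strictly increasing with constant step")
  structure(data.frame(time = time, p_vent = p_vent, p_art = p_art,
                       flow = flow),
            sampling_rate = 1 / mean(dt), density = density,
            class = c("pulse_waveform", "data.frame"))
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf("<pulse_waveform>  %d samples @ %.6g Hz (%.3g s), density %.4g g/cm^3\n",
              nrow(x), attr(x, "sampling_rate"),
              x$time[nrow(x)] - x$time[1], attr(x, "density")))
  invisible(x)
}

#' Read / write the documented waveform CSV layout
#'
#' Column layout `time_s,p_vent_mmHg,p_art_mmHg,q_mL_s`, comma separated,
#' period decimal, UTF-8.
#'
#' @param waveform A [pulse_waveform()].
#' @param path CSV file path.
#' @param density Fluid density attached on read, g/cm^3.
#' @return `read_waveform_csv()` returns a [pulse_waveform()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  df <- data.frame(time_s = waveform$time, p_vent_mmHg = waveform$p_vent,
                   p_art_mmHg = waveform$p_art, q_mL_s = waveform$flow)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, density = 1.005) {
  df <- read.csv(path)
  need <- c("time_s", "p_vent_mmHg", "p_art_mmHg", "q_mL_s")
  if (!all(need %in% names(df)))
    stop("waveform CSV must have columns: ", paste(need, collapse = ","))
  pulse_waveform(df$time_s, df$p_vent_mmHg, df$p_art_mmHg, df$q_mL_s,
                 density = density)
}

#' Segment a waveform into cardiac cycles
#'
#' Cuts the waveform into consecutive windows of exactly one nominal
#' period (60/`cycle_rate` s), phase-aligned to the upstroke of forward
#' flow: the first crossing of 5\% of peak forward flow that is sustained
#' for at least 5 samples. If the flow never rises (degenerate waveform),
#' alignment falls back to the first sample with a warning.
#'
#' @param waveform A [pulse_waveform()].
#' @param cycle_rate Nominal cycle rate, bpm.
#' @param n_cycles Optional cap on the number of windows returned.
#' @return List of cycle windows; each is a data frame
#'   (`time`, `p_vent`, `p_art`, `flow`) with attributes `period` (s),
#'   `sampling_rate` and `density`.
#' @export
segment_cycles <- function(waveform, cycle_rate, n_cycles = NULL) {
  fs <- attr(waveform, "sampling_rate")
  period <- 60 / cycle_rate
  n_per <- round(fs * period)
  if (nrow(waveform) < n_per)
    stop("waveform shorter than one nominal period")
  q <- waveform$flow
  thr <- 0.05 * max(q, 0)
  start <- 1L
  if (thr > 0) {
    above <- q > thr
    # sustained = above threshold for 5 consecutive samples
    win <- above[1:(length(q) - 4L)]
    for (k in 1:4) win <- win & above[(1 + k):(length(q) - 4L + k)]
    if (any(win)) start <- which(win)[1L]
    # pad the window start slightly before the upstroke so the positive
    # differential pressure period is not clipped by the window boundary
    start <- max(1L, start - as.integer(round(0.01 * n_per)))
  } else {
    warning("no forward flow detected; aligning cycles to the first sample")
  }
  n_avail <- (nrow(waveform) - start + 1L) %/% n_per
  if (n_avail < 1L) stop("no complete cycle after phase alignment")
  if (!is.null(n_cycles)) n_avail <- min(n_avail, n_cycles)
  lapply(seq_len(n_avail), function(k) {
    idx <- start + (k - 1L) * n_per + 0:(n_per - 1L)
    cyc <- waveform[idx, , drop = FALSE]
    rownames(cyc) <- NULL
    structure(cyc, period = n_per / fs, sampling_rate = fs,
              density = attr(waveform, "density"), class = "data.frame")
  })
}

#' Positive differential pressure period
#'
#' Bounds (t1, t2) of the longest contiguous interval on which ventricular
#' pressure exceeds arterial pressure, with sub-sample crossing times by
#' linear interpolation.
#'
#' @param cycle One cycle window from [segment_cycles()].
#' @return Numeric `c(t1, t2)` in s.
#' @export
positive_pressure_period <- function(cycle) {
  t <- cycle$time
  dp <- cycle$p_vent - cycle$p_art
  pos <- dp > 0
  if (!any(pos))
    stop("no positive differential pressure period: valve never loaded forward")
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # longest positive run by duration
  runs <- which(r$values)
  durs <- t[ends[runs]] - t[starts[runs]]
  best <- runs[which.max(durs)]
  i1 <- starts[best]; i2 <- ends[best]
  t1 <- if (i1 == 1L) t[1L] else {
    # linear interpolation of the upward zero crossing in [i1-1, i1]
    t[i1 - 1L] + (0 - dp[i1 - 1L]) / (dp[i1] - dp[i1 - 1L]) * (t[i1] - t[i1 - 1L])
  }
  t2 <- if (i2 == length(t)) t[length(t)] else {
    t[i2] + (0 - dp[i2]) / (dp[i2 + 1L] - dp[i2]) * (t[i2 + 1L] - t[i2])
  }
  c(t1 = unname(t1), t2 = unname(t2))
}

# crop a sampled signal to [t1, t2] with interpolated endpoint values
crop_signal <- function(t, y, t1, t2) {
  inside <- t > t1 & t < t2
  tt <- c(t1, t[inside], t2)
  yy <- c(approx(t, y, t1)$y, y[inside], approx(t, y, t2)$y)
  list(t = tt, y = yy)
}

#' Transvalvular mean pressure gradient
#'
#' Time-averaged ventricular-minus-arterial pressure over the positive
#' differential pressure period, by trapezoidal integration.
#'
#' @param cycle One cycle window from [segment_cycles()].
#' @param pdp Optional precomputed [positive_pressure_period()] bounds.
#' @return TPG in mmHg.
#' @export
tpg <- function(cycle, pdp = positive_pressure_period(cycle)) {
  cr <- crop_signal(cycle$time, cycle$p_vent - cycle$p_art, pdp[1], pdp[2])
  unname(pracma::trapz(cr$t, cr$y) / (pdp[2] - pdp[1]))
}

#' RMS forward flow over the positive differential pressure period
#'
#' \deqn{q_{vRMS} = \sqrt{\int_{t_1}^{t_2} q_v(t)^2\,dt / (t_2 - t_1)}}
#'
#' @inheritParams tpg
#' @return qvRMS in mL/s.
#' @export
qv_rms <- function(cycle, pdp = positive_pressure_period(cycle)) {
  cr <- crop_signal(cycle$time, cycle$flow, pdp[1], pdp[2])
  unname(sqrt(pracma::trapz(cr$t, cr$y^2) / (pdp[2] - pdp[1])))
}

#' Effective orifice area (Gorlin-type)
#'
#' \deqn{EOA = \frac{q_{vRMS}}{51.6\sqrt{TPG/\rho}}}
#' with qvRMS in mL/s, TPG in mmHg and density in g/cm^3; 51.6 is the
#' empirical conversion constant.
#'
#' @param qv_rms RMS forward flow, mL/s.
#' @param tpg Mean transvalvular pressure gradient, mmHg (> 0).
#' @param density Fluid density, g/cm^3 (default 1.005).
#' @return EOA in cm^2.
#' @export
#' @examples
#' eoa(200, 4, 1.005)  # about 1.943 cm^2
eoa <- function(qv_rms, tpg, density = 1.005) {
  if (any(tpg <= 0))
    stop("non-positive pressure gradient: EOA undefined for tpg <= 0")
  if (any(density <= 0)) stop("`density` must be positive")
  qv_rms / (51.6 * sqrt(tpg / density))
}

#' Forward, closing and leakage volumes of one cycle
#'
#' Splits the flow integral of a cycle (aligned to the forward-flow
#' upstroke) into the forward-flow volume, the closing volume (backflow
#' between the end of forward flow and the valve-closure instant) and the
#' leakage volume (backflow over the remainder of the cycle). The closure
#' instant is detected as the first time after peak backflow at which the
#' flow has returned to within `closure_eps` (fraction, default 1\%) of
#' the peak backflow magnitude toward zero, sustained for at least 5
#' samples; if the flow settles on a nonzero leak plateau instead, the
#' first sustained stall of the recovery is used.
#'
#' @param cycle One cycle window from [segment_cycles()].
#' @param closure_eps Closure-detection tolerance as a fraction of peak
#'   backflow magnitude.
#' @return Named numeric: `forward`, `closing`, `leakage` (mL).
#' @export
flow_volumes <- function(cycle, closure_eps = 0.01) {
  t <- cycle$time
  q <- cycle$flow
  if (all(q == 0)) return(c(forward = 0, closing = 0, leakage = 0))
  forward <- pracma::trapz(t, pmax(q, 0))
  # end of the forward phase: first non-positive crossing after peak flow
  ipk <- which.max(q)
  after <- which(q[ipk:length(q)] <= 0)
  if (!length(after)) {
    return(c(forward = forward, closing = 0, leakage = 0))
  }
  i_end <- ipk + after[1L] - 1L      # first sample at/below zero
  neg_idx <- i_end:length(q)
  qn <- q[neg_idx]
  if (all(qn >= 0)) {
    return(c(forward = forward, closing = 0, leakage = 0))
  }
  i_peak_bf <- neg_idx[which.min(qn)]
  peak_mag <- abs(q[i_peak_bf])
  # closure: sustained return to within closure_eps of peak magnitude of zero
  i_close <- NA_integer_
  cand <- i_peak_bf:length(q)
  near0 <- q[cand] >= -closure_eps * peak_mag
  for (i in seq_len(max(0L, length(cand) - 4L))) {
    if (all(near0[i:(i + 4L)])) { i_close <- cand[i]; break }
  }
  if (is.na(i_close)) {
    # leak plateau: first sustained stall of the recovery after peak backflow
    dq <- diff(q[cand])
    stall <- abs(dq) <= 1e-3 * peak_mag
    for (i in seq_len(max(0L, length(stall) - 3L))) {
      if (all(stall[i:(i + 3L)]) && q[cand[i]] > q[i_peak_bf] / 2) {
        i_close <- cand[i]; break
      }
    }
  }
  if (is.na(i_close)) i_close <- length(q)
  closing <- abs(pracma::trapz(t[i_end:i_close], q[i_end:i_close]))
  leakage <- if (i_close < length(q))
    abs(pracma::trapz(t[i_close:length(q)], pmin(q[i_close:length(q)], 0)))
  else 0
  c(forward = forward, closing = closing, leakage = leakage)
}

#' Per-cycle hydrodynamic metrics
#'
#' Assembles the ISO-5840-style metrics of one cycle: TPG, qvRMS, EOA,
#' forward/closing/leakage/regurgitant volumes, regurgitation fraction
#' RF = regurgitant/forward x 100, cardiac output (net forward volume per
#' cycle times cycle rate), MAP (time-average arterial pressure over the
#' whole cycle), systolic fraction (forward-flow duration over the
#' period), and the positive-differential-pressure bounds t1, t2.
#'
#' @param cycle One cycle window from [segment_cycles()].
#' @param density Fluid density, g/cm^3; defaults to the waveform's.
#' @return A one-row data frame of class `cycle_metrics`.
#' @export
cycle_metrics <- function(cycle, density = attr(cycle, "density")) {
  if (is.null(density)) density <- 1.005
  period <- attr(cycle, "period")
  if (is.null(period)) period <- cycle$time[nrow(cycle)] - cycle$time[1]
  pdp <- positive_pressure_period(cycle)
  tpg_v <- tpg(cycle, pdp)
  qrms <- qv_rms(cycle, pdp)
  vols <- flow_volumes(cycle)
  regurg <- vols["closing"] + vols["leakage"]
  rf <- if (vols["forward"] > 0) regurg / vols["forward"] * 100 else NA_real_
  net <- vols["forward"] - regurg
  co <- net * (60 / period) / 1000          # L/min
  map <- mean(cycle$p_art)
  # forward-flow duration: total time with q > 0, sub-sample crossings by
  # linear interpolation (robust to where the cycle window was cut)
  q <- cycle$flow
  t <- cycle$time
  dt_i <- diff(t)
  qa <- q[-length(q)]; qb <- q[-1L]
  both_pos <- qa > 0 & qb > 0
  cross <- (qa > 0) != (qb > 0)
  frac <- ifelse(cross, abs(ifelse(qa > 0, qa, qb)) / abs(qb - qa), 0)
  t_fwd <- sum(dt_i[both_pos]) + sum(dt_i[cross] * frac[cross])
  sys_frac <- t_fwd / period * 100
  out <- data.frame(tpg = tpg_v, qv_rms = qrms,
                    eoa = eoa(qrms, tpg_v, density),
                    forward_volume = unname(vols["forward"]),
                    closing_volume = unname(vols["closing"]),
                    leakage_volume = unname(vols["leakage"]),
                    regurgitant_volume = unname(regurg),
                    rf = unname(rf), cardiac_output = unname(co),
                    map = map, systolic_fraction = sys_frac,
                    t1 = pdp[1], t2 = pdp[2])
  class(out) <- c("cycle_metrics", "data.frame")
  out
}

#' Analyze a whole waveform
#'
#' Convenience wrapper: [segment_cycles()] then [cycle_metrics()] per
#' cycle.
#'
#' @inheritParams segment_cycles
#' @param density Fluid density, g/cm^3.
#' @return A `cycle_metrics` data frame with one row per cycle.
#' @export
analyze_waveform <- function(waveform, cycle_rate, n_cycles = NULL,
                             density = attr(waveform, "density")) {
  cycles <- segment_cycles(waveform, cycle_rate, n_cycles)
  out <- do.call(rbind, lapply(cycles, cycle_metrics, density = density))
  class(out) <- c("cycle_metrics", "data.frame")
  out
}

#' Aggregate per-cycle metrics into a group summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of every metric
#' across cycles/valves of one design group.
#'
#' @param metrics A `cycle_metrics` data frame (rows = cycles).
#' @param label Group label.
#' @return A `group_summary`: list with `label`, `n`, and a data frame
#'   `stats` (metric, mean, sd).
#' @export
aggregate_group <- function(metrics, label = "") {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  stats <- data.frame(metric = names(num),
                      mean = vapply(num, mean, numeric(1)),
                      sd = if (nrow(metrics) > 1L)
                        vapply(num, sd, numeric(1)) else 0)
  rownames(stats) <- NULL
  structure(list(label = label, n = nrow(metrics), stats = stats,
                 n1_flag = nrow(metrics) == 1L),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary %s>  n = %d%s\n", x$label, x$n,
              if (x$n1_flag) " (single observation; SD reported as 0)" else ""))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA across groups of values (equal variances
#' assumed), returning the F statistic and p-value.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each n >= 2).
#' @return List with `F`, `p`, `df` (between, within).
#' @export
#' @examples
#' one_way_anova(list(rnorm(10), rnorm(10, 1)))
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (all(vapply(groups, var, numeric(1)) == 0)) {
    if (var(vapply(groups, mean, numeric(1))) == 0)
      stop("degenerate input: zero variance within and between all groups")
    means <- vapply(groups, mean, numeric(1))
    if (var(means) > 0) return(list(F = Inf, p = 0,
                                    df = c(length(groups) - 1L,
                                           sum(lengths(groups)) - length(groups))))
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Two-sided F test for equality of variances
#'
#' Reports F as the larger sample variance over the smaller and the
#' two-sided p-value from the F distribution.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return List with `F`, `p`, `df`.
#' @export
variance_f_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  vt <- var.test(a, b)
  f_big <- max(va, vb) / min(va, vb)
  list(F = f_big, p = unname(vt$p.value),
       df = if (va >= vb) c(length(a) - 1L, length(b) - 1L)
            else c(length(b) - 1L, length(a) - 1L))
}
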