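#' Pulse-duplicator settings for the synthetic waveform generator
#'
#' Target conditions of a right-heart normotensive pulse-duplicator run:
#' cardiac output 5.0 L/min, heart rate 70 bpm, 35\% systolic time span,
#' mean arterial pressure 20 mmHg, with pulmonary-artery end-diastolic
#' pressure and right-ventricular peak systolic pressure inside the ISO
#' normotensive ranges (8-15 and 18-35 mmHg respectively).
#'
#' @param cardiac_output_target L/min (net forward output).
#' @param heart_rate bpm.
#' @param systolic_fraction Percent of the cycle spent in forward flow.
#' @param map_target Whole-cycle mean arterial pressure, mmHg.
#' @param tpg_target Mean forward transvalvular gradient, mmHg.
#' @param pa_end_diastolic Arterial end-diastolic pressure, mmHg.
#' @param peak_systolic_rv Cap for the ventricular peak pressure, mmHg
#'   (validated, not constructed).
#' @param ventricular_diastolic Ventricular diastolic pressure, mmHg.
#' @param closing_volume,leakage_volume Regurgitant volumes per cycle,
#'   mL.
#' @param closing_duration Duration of the closing backflow spike, s.
#' @param noise_sd_pressure,noise_sd_flow Gaussian noise SD added last
#'   (mmHg, mL/s).
#' @param sampling_rate Hz.
#' @param n_cycles Number of cycles generated.
#' @param seed Integer seed (noise reproducibility).
#' @return A `duplicator_settings`.
#' @export
duplicator_settings <- function(cardiac_output_target = 5.0,
                                heart_rate = 70,
                                systolic_fraction = 35,
                                map_target = 20,
                                tpg_target = 2.0,
                                pa_end_diastolic = 12,
                                peak_systolic_rv = 35,
                                ventricular_diastolic = 4,
                                closing_volume = 3,
                                leakage_volume = 2,
                                closing_duration = 0.06,
                                noise_sd_pressure = 0,
                                noise_sd_flow = 0,
                                sampling_rate = 1000,
                                n_cycles = 10L,
                                seed = 1L) {
  s <- list(cardiac_output_target = cardiac_output_target,
            heart_rate = heart_rate, systolic_fraction = systolic_fraction,
            map_target = map_target, tpg_target = tpg_target,
            pa_end_diastolic = pa_end_diastolic,
            peak_systolic_rv = peak_systolic_rv,
            ventricular_diastolic = ventricular_diastolic,
            closing_volume = closing_volume,
            leakage_volume = leakage_volume,
            closing_duration = closing_duration,
            noise_sd_pressure = noise_sd_pressure,
            noise_sd_flow = noise_sd_flow,
            sampling_rate = sampling_rate,
            n_cycles = as.integer(n_cycles), seed = as.integer(seed))
  if (any(unlist(s[c("cardiac_output_target", "heart_rate", "map_target",
                     "tpg_target", "sampling_rate")]) <= 0))
    stop("targets must be positive")
  if (systolic_fraction <= 0 || systolic_fraction >= 100)
    stop("`systolic_fraction` must be in (0, 100)")
  if (closing_volume < 0 || leakage_volume < 0)
    stop("regurgitant volumes must be >= 0")
  structure(s, class = "duplicator_settings")
}

#' @export
print.duplicator_settings <- function(x, ...) {
  cat(sprintf("<duplicator_settings>  CO %g L/min, HR %g bpm, MAP %g mmHg, systole %g%%\n",
              x$cardiac_output_target, x$heart_rate, x$map_target,
              x$systolic_fraction))
  cat(sprintf("  TPG %g mmHg, closing %g mL, leakage %g mL, %g Hz x %d cycles, seed %d\n",
              x$tpg_target, x$closing_volume, x$leakage_volume,
              x$sampling_rate, x$n_cycles, x$seed))
  invisible(x)
}

# piecewise waveform template of one cycle, evaluated at local times tt;
# per-cycle tpg/closing/leakage allow cycle-to-cycle variation in cohorts
cycle_template <- function(tt, s, tpg_c, v_close, v_leak) {
  T_cyc <- 60 / s$heart_rate
  Ts <- s$systolic_fraction / 100 * T_cyc
  tc <- s$closing_duration
  tg <- 0.02                                   # zero-flow gap after closure
  if (Ts + tc + tg >= T_cyc)
    stop("infeasible settings: closing spike does not fit in diastole")
  v_net <- s$cardiac_output_target / s$heart_rate * 1000
  v_fwd <- v_net + v_close + v_leak
  Qp <- pi * v_fwd / (2 * Ts)
  Qc <- 2 * v_close / tc
  t_leak <- T_cyc - Ts - tc - tg
  Ql <- if (v_leak > 0) v_leak / t_leak else 0
  if (Ql > Qp)
    stop("infeasible settings: leakage flow exceeds forward flow bound")

  q <- numeric(length(tt))
  sys <- tt < Ts
  q[sys] <- Qp * sin(pi * tt[sys] / Ts)
  spike <- tt >= Ts & tt < Ts + tc
  x <- (tt[spike] - Ts) / tc
  q[spike] <- -Qc * (1 - abs(2 * x - 1))
  leak <- tt >= Ts + tc + tg
  q[leak] <- -Ql

  # arterial pressure: half-sine-ish systolic rise, exponential diastolic
  # decay to the end-diastolic level; pulse amplitude solved so the
  # whole-cycle mean is exactly map_target
  g <- numeric(length(tt))
  g[sys] <- sin(pi * tt[sys] / (1.4 * Ts))
  g_ts <- sin(pi / 1.4)
  dia <- !sys
  g[dia] <- g_ts * exp(-3 * (tt[dia] - Ts) / (T_cyc - Ts))
  w <- (1.4 * Ts / pi * (1 - cos(pi / 1.4)) +
          g_ts * (T_cyc - Ts) * (1 - exp(-3)) / 3) / T_cyc
  dP_pulse <- (s$map_target - s$pa_end_diastolic) / w
  if (dP_pulse < 0)
    stop("infeasible settings: map_target below pa_end_diastolic")
  p_art <- s$pa_end_diastolic + dP_pulse * g

  # ventricular pressure: arterial plus a half-sine forward gradient whose
  # PDP mean is tpg_c; fast exponential relaxation to the diastolic level
  p_vent <- numeric(length(tt))
  p_vent[sys] <- p_art[sys] + tpg_c * (pi / 2) * sin(pi * tt[sys] / Ts)
  pa_ts <- s$pa_end_diastolic + dP_pulse * g_ts
  tau_r <- 0.02
  p_vent[dia] <- s$ventricular_diastolic +
    (pa_ts - s$ventricular_diastolic) * exp(-(tt[dia] - Ts) / tau_r)
  list(q = q, p_art = p_art, p_vent = p_vent)
}

#' Generate a synthetic pulse-duplicator waveform
#'
#' Builds a deterministic piecewise waveform per cycle: forward flow is a
#' half-sine over the systolic fraction scaled so the net forward volume
#' matches the cardiac-output target; the closing volume is a triangular
#' backflow spike immediately post-systole; leakage is a constant
#' backflow over the remaining diastole (after a short zero-flow gap at
#' valve closure). Arterial pressure is a systolic bump with exponential
#' diastolic decay whose whole-cycle mean equals `map_target` exactly;
#' ventricular pressure adds a half-sine forward gradient with
#' positive-differential-period mean `tpg_target` and relaxes to the
#' ventricular diastolic level in diastole. Gaussian noise is added last.
#' At zero noise the analyzer recovers CO, MAP, HR, systolic fraction,
#' TPG and RF within 1\% of the targets.
#'
#' @param settings A [duplicator_settings()].
#' @param tpg Optional per-cycle TPG values, mmHg (recycled; default
#'   `settings$tpg_target`).
#' @param closing_volume,leakage_volume Optional per-cycle volumes, mL.
#' @return A [pulse_waveform()].
#' @export
#' @examples
#' wf <- generate_waveform(duplicator_settings())
#' wf
generate_waveform <- function(settings,
                              tpg = settings$tpg_target,
                              closing_volume = settings$closing_volume,
                              leakage_volume = settings$leakage_volume) {
  stopifnot(inherits(settings, "duplicator_settings"))
  s <- settings
  T_cyc <- 60 / s$heart_rate
  n_per <- round(s$sampling_rate * T_cyc)
  dt <- 1 / s$sampling_rate
  nc <- s$n_cycles
  tpg <- rep_len(tpg, nc)
  closing_volume <- rep_len(closing_volume, nc)
  leakage_volume <- rep_len(leakage_volume, nc)
  tt_local <- (0:(n_per - 1L)) * dt
  parts <- lapply(seq_len(nc), function(k)
    cycle_template(tt_local, s, tpg[k], closing_volume[k], leakage_volume[k]))
  q <- unlist(lapply(parts, `[[`, "q"))
  p_art <- unlist(lapply(parts, `[[`, "p_art"))
  p_vent <- unlist(lapply(parts, `[[`, "p_vent"))
  tt <- (seq_along(q) - 1L) * dt
  if (s$noise_sd_pressure > 0 || s$noise_sd_flow > 0) {
    set.seed(s$seed)
    p_vent <- p_vent + rnorm(length(q), sd = s$noise_sd_pressure)
    p_art <- p_art + rnorm(length(q), sd = s$noise_sd_pressure)
    q <- q + rnorm(length(q), sd = s$noise_sd_flow)
  }
  if (max(p_vent) > s$peak_systolic_rv + 1e-9)
    warning(sprintf("ventricular peak %.1f mmHg exceeds the configured cap %g mmHg",
                    max(p_vent), s$peak_systolic_rv))
  pulse_waveform(tt, p_vent, p_art, q)
}

# truncated-normal draws (lower bound), simple rejection
rtruncnorm_lb <- function(n, mean, sd, lb = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lb])
  }
  out[seq_len(n)]
}

#' Group specification for synthetic cohorts
#'
#' Per-group hydrodynamic summary parameters (mean and SD of RF, TPG and
#' EOA) driving the cohort generator. [group_specs()] returns the
#' packaged specifications of the seven reference groups.
#'
#' @param label Group label.
#' @param rf_mean,rf_sd Regurgitation fraction, percent.
#' @param tpg_mean,tpg_sd Transvalvular gradient, mmHg.
#' @param eoa_mean,eoa_sd Effective orifice area, cm^2 (descriptive
#'   metadata; the generated EOA follows from the flow shape and the
#'   drawn TPG).
#' @param n_valves,n_cycles Cohort size.
#' @return A `group_spec`.
#' @export
group_spec <- function(label, rf_mean, rf_sd, tpg_mean, tpg_sd,
                       eoa_mean = NA, eoa_sd = NA, n_valves = 3L,
                       n_cycles = 10L) {
  if (rf_sd < 0 || tpg_sd < 0) stop("SDs must be >= 0")
  structure(list(label = label, rf_mean = rf_mean, rf_sd = rf_sd,
                 tpg_mean = tpg_mean, tpg_sd = tpg_sd,
                 eoa_mean = eoa_mean, eoa_sd = eoa_sd,
                 n_valves = as.integer(n_valves),
                 n_cycles = as.integer(n_cycles)),
            class = "group_spec")
}

#' @rdname group_spec
#' @export
group_specs <- function() {
  tab <- data.frame(
    label = paste0("G", 0:6),
    rf_mean = c(18.54, 11.19, 10.41, 10.10, 9.66, 9.22, 8.22),
    rf_sd = c(8.05, 6.75, 2.62, 2.51, 2.55, 1.28, 1.27),
    tpg_mean = c(1.49, 1.89, 1.64, 1.25, 1.98, 2.00, 3.06),
    tpg_sd = c(0.64, 0.19, 0.76, 0.29, 0.23, 0.24, 1.00),
    eoa_mean = c(3.79, 3.67, 3.56, 3.58, 3.64, 3.61, 3.26),
    eoa_sd = c(0.26, 0.33, 0.44, 0.55, 0.23, 0.17, 0.71))
  out <- lapply(seq_len(nrow(tab)), function(i)
    do.call(group_spec, as.list(tab[i, ])))
  names(out) <- tab$label
  out
}

#' Generate a synthetic valve cohort for one group
#'
#' Draws per-cycle RF and TPG from truncated-normal (>= 0) distributions
#' at the group's mean/SD, maps each cycle's RF to closing and leakage
#' volumes at a fixed closing:leakage ratio, and (optionally) renders one
#' multi-cycle waveform per valve. Fully reproducible from the seed.
#'
#' @param spec A [group_spec()].
#' @param seed Integer seed.
#' @param settings Base [duplicator_settings()] (heart rate, CO, MAP,
#'   sampling rate...).
#' @param closing_fraction Closing share of the regurgitant volume
#'   (default 0.6).
#' @param waveforms If `FALSE`, skip waveform rendering and return the
#'   drawn per-cycle values only (fast path for statistical studies).
#' @return List with `draws` (data frame: valve, cycle, rf, tpg,
#'   closing_volume, leakage_volume) and `waveforms` (list of
#'   [pulse_waveform()] per valve, or `NULL`).
#' @export
generate_cohort <- function(spec, seed = 1L,
                            settings = duplicator_settings(),
                            closing_fraction = 0.6, waveforms = TRUE) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(seed)
  n <- spec$n_valves * spec$n_cycles
  rf <- rtruncnorm_lb(n, spec$rf_mean, spec$rf_sd, 0)
  tpg <- rtruncnorm_lb(n, spec$tpg_mean, spec$tpg_sd, 0.05)
  v_net <- settings$cardiac_output_target / settings$heart_rate * 1000
  # RF = Vr / Vf with Vf = Vnet + Vr  =>  Vr = Vnet * RF / (100 - RF)
  v_reg <- v_net * rf / (100 - rf)
  draws <- data.frame(valve = rep(seq_len(spec$n_valves),
                                  each = spec$n_cycles),
                      cycle = rep(seq_len(spec$n_cycles), spec$n_valves),
                      rf = rf, tpg = tpg,
                      closing_volume = closing_fraction * v_reg,
                      leakage_volume = (1 - closing_fraction) * v_reg)
  wfs <- NULL
  if (waveforms) {
    s <- settings
    s$n_cycles <- spec$n_cycles
    wfs <- lapply(seq_len(spec$n_valves), function(v) {
      d <- draws[draws$valve == v, ]
      generate_waveform(s, tpg = d$tpg, closing_volume = d$closing_volume,
                        leakage_volume = d$leakage_volume)
    })
  }
  list(label = spec$label, draws = draws, waveforms = wfs, seed = seed)
}

#' Generate a wheeled free-edge trace of known arc length
#'
#' Constructs a planar polyline between the endpoints of an ideal
#' straight free edge whose polyline arc length equals exactly
#' `wheel_factor * ideal_length`: a seeded spiral-like transverse
#' perturbation is scaled by root finding until the length matches to
#' machine precision. Through the Pinwheeling Index this gives the exact
#' value \eqn{PI = (1 - 1/\mathrm{wheel\_factor}) \times 100}.
#'
#' @param ideal_length Ideal edge length, mm (> 0).
#' @param wheel_factor Length multiplier >= 1.
#' @param n_points Number of polyline points (>= 3).
#' @param seed Integer seed for the perturbation shape.
#' @return A `free_edge_trace` (n x 2 matrix).
#' @export
#' @examples
#' tr <- generate_wheeled_edge(13, 1.25, 101, seed = 2)
#' polyline_length(tr) / 13  # 1.25
generate_wheeled_edge <- function(ideal_length, wheel_factor, n_points = 101L,
                                  seed = 1L) {
  if (ideal_length <= 0) stop("`ideal_length` must be positive")
  if (wheel_factor < 1) stop("`wheel_factor` must be >= 1")
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("`n_points` must be >= 3")
  u <- seq(0, 1, length.out = n_points)
  x <- ideal_length * u
  if (wheel_factor == 1)
    return(structure(cbind(x, 0 * x), degenerate = FALSE,
                     class = c("free_edge_trace", "matrix")))
  set.seed(seed)
  k <- sample(2:4, 1)
  phase <- runif(1, 0, pi)
  base <- sin(k * pi * u + phase) - (1 - u) * sin(phase) -
    u * sin(k * pi + phase)          # vanishes at both endpoints
  len_at <- function(a) polyline_length(cbind(x, a * base * ideal_length))
  target <- wheel_factor * ideal_length
  hi <- 1
  while (len_at(hi) < target) hi <- hi * 2
  a <- uniroot(function(a) len_at(a) - target, c(0, hi),
               tol = .Machine$double.eps^0.75)$root
  structure(cbind(x, a * base * ideal_length), degenerate = FALSE,
            class = c("free_edge_trace", "matrix"))
}
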