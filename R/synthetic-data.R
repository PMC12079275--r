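# Synthetic-data generators. The raw recordings behind the published figures
# are not deposited, so every analysis stage is exercised against generated
# traces whose statistical structure matches the figure-caption summaries.
# Every generator is a pure function of its spec (including the seed): the
# caller's RNG state is never consulted or modified.

#' Specification of a regular-spiking membrane-potential trace
#'
#' Defaults emulate the spontaneous action-potential-like spiking of Glu:Phe
#' proteinoid microspheres: spikes of 25.3 +/- 5.2 mV above a ~25 mV
#' baseline, mean interspike interval 52.4 s, logged at 2.5 Hz (dt = 0.4 s).
#' Interspike intervals are gamma-distributed with the stated mean and
#' coefficient of variation (the recordings are quasi-periodic; `isi_cv`
#' defaults to 0.2). Each spike rises within one sample and repolarises
#' exponentially with time constant `decay_frac * isi_mean_s`.
#'
#' @param baseline_mV Resting potential.
#' @param spike_amp_mean_mV,spike_amp_sd_mV Spike amplitude distribution.
#' @param isi_mean_s Mean interspike interval (positive).
#' @param isi_cv Coefficient of variation of the interval distribution
#'   (0 = strictly periodic).
#' @param noise_sd_mV Additive Gaussian baseline noise.
#' @param dt_s Sampling interval (positive).
#' @param duration_s Recording length (> dt_s).
#' @param decay_frac Repolarisation time constant as a fraction of
#'   `isi_mean_s`.
#' @param seed RNG seed.
#' @return A `trace_spec` list.
#' @export
spiking_trace_spec <- function(baseline_mV = 25, spike_amp_mean_mV = 25.3,
                               spike_amp_sd_mV = 5.2, isi_mean_s = 52.4,
                               isi_cv = 0.2, noise_sd_mV = 1, dt_s = 0.4,
                               duration_s = 20000, decay_frac = 0.2,
                               seed = 42L) {
  check_positive(dt_s, "dt_s")
  check_positive(isi_mean_s, "isi_mean_s")
  check_nonneg(noise_sd_mV, "noise_sd_mV")
  check_nonneg(isi_cv, "isi_cv")
  if (!is.numeric(duration_s) || duration_s <= dt_s) {
    abort("`duration_s` must exceed `dt_s`.", class = "protoelec_invalid_spec")
  }
  structure(list(baseline_mV = baseline_mV,
                 spike_amp_mean_mV = spike_amp_mean_mV,
                 spike_amp_sd_mV = spike_amp_sd_mV,
                 isi_mean_s = isi_mean_s, isi_cv = isi_cv,
                 noise_sd_mV = noise_sd_mV, dt_s = dt_s,
                 duration_s = duration_s, decay_frac = decay_frac,
                 seed = seed), class = "trace_spec")
}

#' Generate a regular-spiking trace
#'
#' @param spec A [spiking_trace_spec()].
#' @param channel Channel name for the output column.
#' @return Multichannel trace tibble: `time_s` and one channel column (mV),
#'   `floor(duration_s / dt_s)` rows.
#' @examples
#' tr <- gen_spiking_trace(spiking_trace_spec(duration_s = 1000, seed = 7))
#' spike_stats(tr)
#' @export
gen_spiking_trace <- function(spec, channel = "ch1") {
  stopifnot(inherits(spec, "trace_spec"))
  n <- floor(spec$duration_s / spec$dt_s)
  tvec <- (seq_len(n) - 1) * spec$dt_s
  with_seed(spec$seed, {
    # draw interspike intervals until the recording is covered
    isis <- numeric(0)
    while (sum(isis) < spec$duration_s) {
      k <- max(64, ceiling(2 * spec$duration_s / spec$isi_mean_s))
      new <- if (spec$isi_cv == 0) {
        rep(spec$isi_mean_s, k)
      } else {
        shape <- 1 / spec$isi_cv^2
        rgamma(k, shape = shape, scale = spec$isi_mean_s / shape)
      }
      isis <- c(isis, new)
    }
    spike_times <- cumsum(isis)
    spike_times <- spike_times[spike_times < spec$duration_s - spec$dt_s]
    amps <- rnorm(length(spike_times), spec$spike_amp_mean_mV,
                  spec$spike_amp_sd_mV)
    v <- rep(spec$baseline_mV, n)
    tau <- spec$decay_frac * spec$isi_mean_s
    kern_len <- min(n, ceiling(6 * tau / spec$dt_s))
    kern <- exp(-(seq_len(kern_len) - 1) * spec$dt_s / tau)
    for (s in seq_along(spike_times)) {
      i0 <- floor(spike_times[s] / spec$dt_s) + 1
      idx <- i0:min(n, i0 + kern_len - 1)
      v[idx] <- v[idx] + amps[s] * kern[seq_along(idx)]
    }
    if (spec$noise_sd_mV > 0) v <- v + rnorm(n, 0, spec$noise_sd_mV)
    out <- tibble(time_s = tvec)
    out[[channel]] <- v
    out
  })
}

#' Generate a multiphasic (plateau / bistable) trace
#'
#' Concatenates piecewise segments. Each phase is a row of `phase_table`
#' with `duration_s`, `target_mV` and `shape`:
#' \describe{
#'   \item{`"constant"`}{hold at `target_mV` for the whole phase;}
#'   \item{`"ramp"`}{linear from the previous level to `target_mV`;}
#'   \item{`"step"`}{jump to `target_mV` immediately and hold;}
#'   \item{`"exp"`}{exponential approach to `target_mV` with time constant
#'     `duration_s / 5`.}
#' }
#' This reproduces both the class-2 plateau profile of pure actin (ramp,
#' metastable plateau, sharp hyperpolarising transition, steady state) and
#' bistable multiphasic profiles with repeated state transitions.
#'
#' @param phase_table Data frame with columns `duration_s`, `target_mV`,
#'   `shape` (non-empty; durations positive).
#' @param noise_sd_mV Additive Gaussian noise.
#' @param dt_s Sampling interval.
#' @param seed RNG seed (only used when `noise_sd_mV > 0`).
#' @param start_mV Level before the first phase (ramp origin).
#' @param channel Output channel name.
#' @return Multichannel trace tibble (`time_s` + one channel).
#' @export
gen_multiphasic_trace <- function(phase_table, noise_sd_mV = 0, dt_s = 0.4,
                                  seed = 1L, start_mV = 0, channel = "ch1") {
  phase_table <- as.data.frame(phase_table)
  if (nrow(phase_table) == 0) {
    abort("phase table is empty.", class = "protoelec_invalid_spec")
  }
  if (any(phase_table$duration_s <= 0)) {
    abort("phase durations must be positive.", class = "protoelec_invalid_spec")
  }
  check_positive(dt_s, "dt_s")
  check_nonneg(noise_sd_mV, "noise_sd_mV")
  level <- start_mV
  segs <- vector("list", nrow(phase_table))
  for (i in seq_len(nrow(phase_table))) {
    ph <- phase_table[i, ]
    m <- max(1, floor(ph$duration_s / dt_s))
    seg <- switch(as.character(ph$shape),
      constant = rep(ph$target_mV, m),
      step     = rep(ph$target_mV, m),
      ramp     = level + (ph$target_mV - level) * seq_len(m) / m,
      exp      = ph$target_mV + (level - ph$target_mV) *
                   exp(-(seq_len(m)) * dt_s / (ph$duration_s / 5)),
      abort(sprintf("unknown phase shape '%s'.", ph$shape),
            class = "protoelec_invalid_spec")
    )
    segs[[i]] <- seg
    level <- seg[m]
  }
  v <- unlist(segs)
  if (noise_sd_mV > 0) {
    v <- with_seed(seed, v + rnorm(length(v), 0, noise_sd_mV))
  }
  out <- tibble(time_s = (seq_along(v) - 1) * dt_s)
  out[[channel]] <- v
  out
}

#' Canonical multiphasic phase tables
#'
#' `"plateau"`: the class-2 actin profile (depolarisation at 8 mV/min to a
#' ~40 mV metastable plateau held ~5000 s, a sharp transition to -60 mV,
#' settling to a -20 mV steady state). `"bistable"`: repeated transitions
#' between two stable levels.
#'
#' @param profile `"plateau"` or `"bistable"`.
#' @return A phase-table tibble for [gen_multiphasic_trace()].
#' @export
multiphasic_profile <- function(profile = c("plateau", "bistable")) {
  profile <- match.arg(profile)
  switch(profile,
    plateau = tibble(
      duration_s = c(300, 5000, 400, 4000),
      target_mV = c(40, 40, -60, -20),
      shape = c("ramp", "constant", "step", "exp")
    ),
    bistable = tibble(
      duration_s = c(2000, 2000, 2000, 2000, 2000),
      target_mV = c(40, -40, 40, -40, 40),
      shape = "step"
    )
  )
}

#' Specification of a square-wave stimulation session
#'
#' Defaults emulate the published stimulation experiment: a 1000 mV square
#' wave at 50% duty cycle applied for 20 s, with four recorded channels
#' (C-F) whose baselines, input-output attenuations, onset latencies and
#' recovery times match the caption statistics (channel C baseline
#' -6.22 +/- 0.81 mV and attenuation 205.63 mV; channel F baseline
#' -82.74 +/- 1.63 mV and attenuation 282.15 mV; latencies 4.2-7.8 ms and
#' recoveries 10.5-15.3 ms across channels, interior channels
#' interpolated). Sessions are generated at dt = 1 ms so that ms-scale
#' latencies are resolvable.
#'
#' @param stim_amplitude_mV Square-wave amplitude.
#' @param duty_fraction On-fraction of each period, in (0, 1).
#' @param period_s Stimulation period.
#' @param channels Tibble with columns `channel`, `baseline_mean_mV`,
#'   `baseline_sd_mV`, `attenuation_mV`, `latency_ms`, `recovery_ms`.
#' @param dt_s Sampling interval; must satisfy `dt_s <= min(latency) / 4`.
#' @param duration_s Session length.
#' @param seed RNG seed.
#' @return A `stimulation_spec` list.
#' @export
stimulation_spec <- function(stim_amplitude_mV = 1000, duty_fraction = 0.5,
                             period_s = 4, channels = NULL, dt_s = 0.001,
                             duration_s = 20, seed = 7L) {
  if (duty_fraction <= 0 || duty_fraction >= 1) {
    abort("`duty_fraction` must lie in (0, 1).", class = "protoelec_invalid_spec")
  }
  check_positive(period_s, "period_s")
  check_positive(dt_s, "dt_s")
  if (is.null(channels)) {
    channels <- tibble(
      channel = c("chC", "chD", "chE", "chF"),
      baseline_mean_mV = c(-6.22, -66.78, -66.73, -82.74),
      baseline_sd_mV = c(0.81, 1.77, 1.72, 1.63),
      attenuation_mV = c(205.63, 231.14, 256.65, 282.15),
      latency_ms = c(4.2, 5.4, 6.6, 7.8),
      recovery_ms = c(10.5, 12.1, 13.7, 15.3)
    )
  }
  if (dt_s > min(channels$latency_ms) / 1000 / 4) {
    abort("`dt_s` too coarse: must be at most a quarter of the smallest latency.",
          class = "protoelec_invalid_spec")
  }
  structure(list(stim_amplitude_mV = stim_amplitude_mV,
                 duty_fraction = duty_fraction, period_s = period_s,
                 channels = channels, dt_s = dt_s, duration_s = duration_s,
                 seed = seed), class = "stimulation_spec")
}

#' Generate a stimulation session
#'
#' The stimulus is a 0/amplitude square wave. Each channel's deterministic
#' response is `baseline + (amplitude - attenuation) * gate`, with the gate
#' delayed by the channel latency; after the stimulus switches off the
#' response decays exponentially back to baseline with time constant
#' `recovery_ms / ln(10)` (so it re-enters the 10% band of baseline exactly
#' `recovery_ms` after the falling edge). Gaussian noise with the channel
#' baseline sd is added throughout.
#'
#' @param spec A [stimulation_spec()].
#' @return List with `stimulus` (tibble `time_s`, `stim_mV`) and `response`
#'   (multichannel trace tibble on the same time base).
#' @export
gen_stimulation_session <- function(spec) {
  stopifnot(inherits(spec, "stimulation_spec"))
  n <- floor(spec$duration_s / spec$dt_s)
  tvec <- (seq_len(n) - 1) * spec$dt_s
  gate <- (tvec %% spec$period_s) < spec$duty_fraction * spec$period_s
  stim <- spec$stim_amplitude_mV * gate
  response <- tibble(time_s = tvec)
  with_seed(spec$seed, {
    for (i in seq_len(nrow(spec$channels))) {
      ch <- spec$channels[i, ]
      lag_n <- round(ch$latency_ms / 1000 / spec$dt_s)
      gate_d <- c(rep(FALSE, lag_n), gate)[seq_len(n)]
      evoked <- spec$stim_amplitude_mV - ch$attenuation_mV
      tau <- ch$recovery_ms / 1000 / log(10)
      decay <- exp(-spec$dt_s / tau)
      v <- numeric(n)
      v[1] <- if (gate_d[1]) evoked else 0
      for (j in 2:n) {
        v[j] <- if (gate_d[j]) evoked else v[j - 1] * decay
      }
      v <- v + ch$baseline_mean_mV
      if (ch$baseline_sd_mV > 0) v <- v + rnorm(n, 0, ch$baseline_sd_mV)
      response[[ch$channel]] <- v
    }
  })
  list(stimulus = tibble(time_s = tvec, stim_mV = stim), response = response)
}

#' Generate a synthetic impedance spectrum from a circuit model
#'
#' Evaluates [circuit_impedance()] and optionally corrupts it with
#' multiplicative complex Gaussian noise: each impedance is scaled by
#' `1 + e`, where the real and imaginary parts of `e` are independent
#' N(0, noise_frac) draws.
#'
#' @param model A [circuit_model()].
#' @param frequencies Positive, sorted frequencies in Hz.
#' @param noise_frac Relative noise level (0 = exact model output).
#' @param seed RNG seed.
#' @return Spectrum tibble `freq_hz`, `z_real_ohm`, `z_imag_ohm`.
#' @export
gen_impedance_spectrum <- function(model, frequencies, noise_frac = 0, seed = 1L) {
  sp <- circuit_impedance(model, frequencies)
  if (noise_frac > 0) {
    z <- complex(real = sp$z_real_ohm, imaginary = sp$z_imag_ohm)
    z <- with_seed(seed, {
      z * (1 + complex(real = rnorm(length(z), 0, noise_frac),
                       imaginary = rnorm(length(z), 0, noise_frac)))
    })
    sp$z_real_ohm <- Re(z)
    sp$z_imag_ohm <- Im(z)
  }
  sp
}

#' Generate repeated current-voltage sweep cycles
#'
#' Each cycle traverses a triangular voltage path 0 -> +v_range -> -v_range
#' -> 0 at the given scan rate. The cycle resistance drifts linearly,
#' `R_c = r0 + drift_per_cycle * (c - 1) + N(0, r_noise_sd)`, and the current
#' is `I = V / R_c` plus an optional pinched hysteresis loop offset
#' `hysteresis_width * dir * 4 u (1 - u)` with `u = |V| / v_range` and `dir`
#' the sweep direction (the loop closes at the origin and is widest at half
#' range, as in memristive I-V characteristics).
#'
#' @param r0_ohm Base resistance (positive).
#' @param drift_per_cycle Resistance drift per cycle (ohm).
#' @param hysteresis_width Hysteresis current half-width (A).
#' @param n_cycles Number of cycles (>= 1; default 50).
#' @param v_range Sweep limit in volt (default +/- 5 V).
#' @param scan_rate Volt per second (default 0.1, i.e. 100 mV/s).
#' @param r_noise_sd Cycle-resistance noise sd (ohm).
#' @param dt_s Sampling interval.
#' @param seed RNG seed.
#' @return Tibble with `cycle`, `time_s`, `v_V`, `i_A` and a `scan_rate_V_s`
#'   attribute.
#' @export
gen_iv_sweeps <- function(r0_ohm, drift_per_cycle = 0, hysteresis_width = 0,
                          n_cycles = 50, v_range = 5, scan_rate = 0.1,
                          r_noise_sd = 0, dt_s = 0.5, seed = 1L) {
  check_positive(r0_ohm, "r0_ohm")
  check_positive(scan_rate, "scan_rate")
  check_positive(v_range, "v_range")
  if (n_cycles < 1) {
    abort("need at least one cycle.", class = "protoelec_invalid_spec")
  }
  cycle_t <- 4 * v_range / scan_rate
  m <- floor(cycle_t / dt_s)
  tt <- (seq_len(m) - 1) * dt_s
  # triangular path 0 -> +V -> -V -> 0
  phase <- (tt / cycle_t) %% 1
  vpath <- ifelse(phase < 0.25, 4 * phase,
           ifelse(phase < 0.75, 2 - 4 * phase, -4 + 4 * phase)) * v_range
  dir <- sign(c(diff(vpath), vpath[1] - vpath[m]))
  dir[dir == 0] <- 1
  # pinched hysteresis loop: no loop opening at the origin, widest at half
  # range (normalised to peak 1), as in memristive I-V characteristics
  u <- abs(vpath) / v_range
  loop_shape <- 4 * u * (1 - u)
  r_cycles <- with_seed(seed, {
    r0_ohm + drift_per_cycle * (seq_len(n_cycles) - 1) +
      if (r_noise_sd > 0) rnorm(n_cycles, 0, r_noise_sd) else 0
  })
  if (any(r_cycles <= 0)) {
    abort("drift/noise drove a cycle resistance non-positive.",
          class = "protoelec_domain_error")
  }
  out <- purrr::map_dfr(seq_len(n_cycles), function(c) {
    i <- vpath / r_cycles[c] + hysteresis_width * dir * loop_shape
    tibble(cycle = c, time_s = (c - 1) * cycle_t + tt, v_V = vpath, i_A = i)
  })
  attr(out, "scan_rate_V_s") <- scan_rate
  out
}

#' Specification of a coupled temperature/pH log
#'
#' Defaults emulate the published environment logs: temperature oscillating
#' with a ~90 min dominant period (published range 72.4-123.7 min), pH
#' averaging 7.88 +/- 0.05 and tracking the temperature oscillation with a
#' positive lag (pH adjustments occur after temperature swings), both logged
#' at 1 Hz.
#'
#' @param temp_mean_C,temp_amp_C Temperature mean and oscillation amplitude.
#' @param temp_period_min Dominant temperature period (minutes).
#' @param ph_mean,ph_amp pH mean and oscillation amplitude.
#' @param lag_min pH lag behind temperature in minutes (positive = pH lags).
#' @param noise_sd_temp,noise_sd_ph Additive Gaussian noise sd per signal.
#' @param drift_temp_C_per_h,drift_ph_per_h Optional slow linear drifts, as
#'   seen superposed on the recorded oscillations (default 0: stationary).
#' @param dt_s Sampling interval (default 1 s).
#' @param duration_s Log length (default 6 h).
#' @param seed RNG seed.
#' @return An `env_spec` list.
#' @export
env_spec <- function(temp_mean_C = 25, temp_amp_C = 0.5, temp_period_min = 90,
                     ph_mean = 7.88, ph_amp = 0.05, lag_min = 15,
                     noise_sd_temp = 0.02, noise_sd_ph = 0.005,
                     drift_temp_C_per_h = 0, drift_ph_per_h = 0,
                     dt_s = 1, duration_s = 6 * 3600, seed = 1L) {
  check_positive(temp_period_min, "temp_period_min")
  check_positive(dt_s, "dt_s")
  if (!is.finite(lag_min)) {
    abort("`lag_min` must be finite.", class = "protoelec_invalid_spec")
  }
  check_nonneg(noise_sd_temp, "noise_sd_temp")
  check_nonneg(noise_sd_ph, "noise_sd_ph")
  structure(list(temp_mean_C = temp_mean_C, temp_amp_C = temp_amp_C,
                 temp_period_min = temp_period_min, ph_mean = ph_mean,
                 ph_amp = ph_amp, lag_min = lag_min,
                 noise_sd_temp = noise_sd_temp, noise_sd_ph = noise_sd_ph,
                 drift_temp_C_per_h = drift_temp_C_per_h,
                 drift_ph_per_h = drift_ph_per_h,
                 dt_s = dt_s, duration_s = duration_s, seed = seed),
            class = "env_spec")
}

#' Generate a coupled temperature/pH log
#'
#' The temperature oscillation is a sinusoid plus a weak second harmonic
#' around the mean; the pH series carries the same oscillatory waveform,
#' scaled to `ph_amp` and delayed by `lag_min` minutes, around `ph_mean`.
#' Independent Gaussian noise is added to each signal.
#'
#' @param spec An [env_spec()].
#' @return Tibble with `time_s`, `temperature_C`, `pH`.
#' @examples
#' env <- gen_env_series(env_spec(duration_s = 3600 * 4))
#' phase_lag(env) / 60 # ~ lag_min
#' @export
gen_env_series <- function(spec) {
  stopifnot(inherits(spec, "env_spec"))
  n <- floor(spec$duration_s / spec$dt_s)
  tvec <- (seq_len(n) - 1) * spec$dt_s
  per_s <- spec$temp_period_min * 60
  osc <- function(t) sin(2 * pi * t / per_s) + 0.2 * sin(4 * pi * t / per_s + 0.5)
  with_seed(spec$seed, {
    temp <- spec$temp_mean_C + spec$temp_amp_C * osc(tvec) +
      spec$drift_temp_C_per_h * tvec / 3600
    ph <- spec$ph_mean + spec$ph_amp * osc(tvec - spec$lag_min * 60) +
      spec$drift_ph_per_h * (tvec - mean(tvec)) / 3600
    if (spec$noise_sd_temp > 0) temp <- temp + rnorm(n, 0, spec$noise_sd_temp)
    if (spec$noise_sd_ph > 0) ph <- ph + rnorm(n, 0, spec$noise_sd_ph)
    tibble(time_s = tvec, temperature_C = temp, pH = ph)
  })
}

#' Generate a decaying capacitance series
#'
#' `C(t) = c0 * exp(-decay_rate * t) + noise`, clipped to stay positive;
#' the distinct decay profiles of the three preparations are emulated by the
#' decay rate. Output feeds [modulate_params()].
#'
#' @param c0 Initial capacitance (any unit; positive).
#' @param decay_rate Exponential decay rate (1/s).
#' @param fluctuation_sd Additive Gaussian noise sd.
#' @param dt_s Sampling interval.
#' @param duration_s Series length.
#' @param seed RNG seed.
#' @return Tibble with `time_s`, `capacitance`.
#' @export
gen_capacitance_series <- function(c0, decay_rate = 0, fluctuation_sd = 0,
                                   dt_s = 1, duration_s = 1000, seed = 1L) {
  check_positive(c0, "c0")
  check_nonneg(decay_rate, "decay_rate")
  check_nonneg(fluctuation_sd, "fluctuation_sd")
  n <- floor(duration_s / dt_s)
  tvec <- (seq_len(n) - 1) * dt_s
  cval <- c0 * exp(-decay_rate * tvec)
  if (fluctuation_sd > 0) {
    cval <- with_seed(seed, cval + rnorm(n, 0, fluctuation_sd))
  }
  cval <- pmax(cval, c0 * 1e-9)
  tibble(time_s = tvec, capacitance = cval)
}
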