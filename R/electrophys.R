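#' Detect action-potential-like spikes in one channel
#'
#' A sample is a spike candidate when it is a local maximum (strictly above
#' its left neighbour, at least as high as its right neighbour) whose height
#' above the local pre-event baseline -- the median of `baseline_pre_n`
#' samples ending `baseline_gap` samples before it -- exceeds
#' `min_prominence_mV`. Candidates are then scanned in time order and any
#' candidate closer than `refractory_s` to the previously accepted spike is
#' dropped.
#'
#' Prominence is measured against the pre-event baseline rather than a
#' centred rolling median because these events depolarise within a sample and
#' repolarise over a sizeable fraction of the interspike interval: a centred
#' median window either contains the spike's own tail (biasing the baseline
#' high at the peak) or, if widened, turns the decay shoulder into spurious
#' candidates. The rise height is free of both artefacts at any interval.
#' The per-spike amplitude uses the same pre-event baseline.
#'
#' @param trace Multichannel trace tibble (`time_s` plus channel columns, mV).
#' @param channel Channel column name.
#' @param min_prominence_mV Minimum rise height above the pre-event baseline.
#' @param refractory_s Minimum separation between accepted spikes (seconds,
#'   must be at least one sample).
#' @param baseline_pre_n,baseline_gap Pre-event baseline window: `baseline_pre_n`
#'   samples ending `baseline_gap` samples before the candidate.
#' @return Tibble with `time_s`, `index`, `amplitude_mV` (one row per spike).
#' @examples
#' tr <- gen_spiking_trace(spiking_trace_spec(duration_s = 2000, seed = 1))
#' detect_spikes(tr, "ch1")
#' @export
detect_spikes <- function(trace, channel, min_prominence_mV = 5,
                          refractory_s = 10,
                          baseline_pre_n = 10, baseline_gap = 2) {
  if (!channel %in% names(trace)) {
    abort(sprintf("unknown channel '%s'.", channel), class = "protoelec_key_error")
  }
  dt <- trace_dt(trace)
  if (refractory_s < dt) {
    abort("`refractory_s` must be at least one sampling interval.",
          class = "protoelec_invalid_spec")
  }
  v <- trace[[channel]]
  n <- length(v)
  pre_median <- function(j) {
    j1 <- max(1, j - baseline_gap - baseline_pre_n + 1)
    j2 <- max(1, j - baseline_gap)
    median(v[j1:j2])
  }

  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[vapply(cand, function(i) v[i] - pre_median(i), numeric(1)) >=
                 min_prominence_mV]

  refr_n <- refractory_s / dt
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr_n) {
      keep <- c(keep, i)
      last <- i
    }
  }

  # Measure the amplitude at the sample terminating the steepest rise next to
  # the detected maximum: for fast-depolarising events this reads the peak
  # without the upward order-statistic bias of taking the noisy local max.
  refined <- vapply(keep, function(i) {
    js <- max(2, i - 3):i
    js[which.max(v[js] - v[js - 1])]
  }, integer(1))
  amp <- vapply(refined, function(j) v[j] - pre_median(j), numeric(1))

  tibble(time_s = trace$time_s[refined], index = refined, amplitude_mV = amp)
}

#' Per-channel spike amplitude and period statistics
#'
#' Runs [detect_spikes()] on every channel and summarises amplitudes and
#' interspike periods (successive spike-time differences). Period statistics
#' are `NA` for channels with fewer than two spikes. For sparsely spiking
#' channels (fewer than `periodogram_min` spikes) a periodogram-based period
#' estimate `period_spectral_s` is also reported. Standard deviations use the
#' sample (n - 1) convention.
#'
#' @param trace Multichannel trace tibble.
#' @param periodogram_min Below this spike count, also estimate the dominant
#'   period spectrally.
#' @param ... Passed to [detect_spikes()].
#' @return Tibble, one row per channel: `channel`, `n_spikes`,
#'   `amp_median_mV`, `amp_mean_mV`, `amp_sd_mV`, `amp_max_mV`,
#'   `period_mean_s`, `period_sd_s`, `period_median_s`, `period_spectral_s`.
#' @export
spike_stats <- function(trace, periodogram_min = 5, ...) {
  dt <- trace_dt(trace)
  purrr::map_dfr(trace_channels(trace), function(ch) {
    sp <- detect_spikes(trace, ch, ...)
    n <- nrow(sp)
    periods <- if (n >= 2) diff(sp$time_s) else numeric(0)
    spectral <- NA_real_
    if (n < periodogram_min && length(trace[[ch]]) >= 64 &&
        sd(trace[[ch]]) > 0) {
      spectral <- tryCatch(dominant_period(trace[[ch]], dt),
                           error = function(e) NA_real_)
    }
    tibble(
      channel = ch,
      n_spikes = n,
      amp_median_mV = if (n > 0) median(sp$amplitude_mV) else NA_real_,
      amp_mean_mV   = if (n > 0) mean(sp$amplitude_mV) else NA_real_,
      amp_sd_mV     = if (n > 1) sd(sp$amplitude_mV) else NA_real_,
      amp_max_mV    = if (n > 0) max(sp$amplitude_mV) else NA_real_,
      period_mean_s   = if (n >= 2) mean(periods) else NA_real_,
      period_sd_s     = if (n >= 3) sd(periods) else NA_real_,
      period_median_s = if (n >= 2) median(periods) else NA_real_,
      period_spectral_s = spectral
    )
  })
}

# Sarle's bimodality coefficient (sample version): (skew^2 + 1) / (kurtosis +
# 3 (n-1)^2 / ((n-2)(n-3))), where kurtosis is the excess kurtosis. Values
# above 0.555 (the uniform distribution's value) suggest bimodality.
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(NA_real_)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  m3 <- mean(z^3)
  m4 <- mean(z^4)
  skew <- m3 * sqrt(n * (n - 1)) / (n - 2)
  exkurt <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (m4 - 3) + 6)
  (skew^2 + 1) / (exkurt + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Classify the excitability regime of a channel
#'
#' Rule-based classifier over the four regimes seen in proteinoid-actin
#' recordings, applied in order:
#' \enumerate{
#'   \item `regular_spiking`: at least 5 detected spikes whose interspike
#'     periods have coefficient of variation below 0.5 (type-I-like sustained
#'     periodic firing);
#'   \item `plateau_class2`: a sustained high state occupying more than 10\%
#'     of the recording followed by a step down to a distinctly lower level
#'     (class-2-like plateau excitability);
#'   \item `bistable`: a bimodal voltage histogram (bimodality coefficient
#'     above 0.555) with at least 2 transitions between the two states;
#'   \item `quiescent` otherwise.
#' }
#'
#' @param trace Multichannel trace tibble with at least 100 samples.
#' @param channel Channel column name.
#' @param ... Passed to [detect_spikes()].
#' @return A single label string.
#' @export
classify_dynamics <- function(trace, channel, ...) {
  if (!channel %in% names(trace)) {
    abort(sprintf("unknown channel '%s'.", channel), class = "protoelec_key_error")
  }
  v <- trace[[channel]]
  if (length(v) < 100) {
    abort("need at least 100 samples to classify dynamics.",
          class = "protoelec_insufficient_data")
  }

  sp <- detect_spikes(trace, channel, ...)
  if (nrow(sp) >= 5) {
    periods <- diff(sp$time_s)
    if (mean(periods) > 0 && sd(periods) / mean(periods) < 0.5) {
      return("regular_spiking")
    }
  }

  # plateau: smoothed trace spends >10% of the recording within the top band,
  # then steps down by >30% of the range and stays lower afterwards
  n <- length(v)
  sm <- runmed(v, k = min(51, if (n %% 2 == 1) n else n - 1), endrule = "median")
  rng <- diff(range(sm))
  if (rng > 0) {
    high <- sm > max(sm) - 0.15 * rng
    r <- rle(high)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    long_high <- which(r$values & r$lengths > 0.1 * n)
    for (k in long_high) {
      after <- seq.int(min(ends[k] + 1, n), n)
      if (length(after) > 0.05 * n &&
          max(sm[after]) < max(sm) - 0.3 * rng) {
        return("plateau_class2")
      }
    }
  }

  bc <- bimodality_coefficient(v)
  if (!is.na(bc) && bc > 0.555) {
    # count transitions across the mid-range with hysteresis of 10% range
    lo_th <- min(v) + 0.4 * diff(range(v))
    hi_th <- min(v) + 0.6 * diff(range(v))
    state <- 0L
    transitions <- 0L
    for (x in v) {
      if (state <= 0 && x > hi_th) {
        if (state == -1L) transitions <- transitions + 1L
        state <- 1L
      } else if (state >= 0 && x < lo_th) {
        if (state == 1L) transitions <- transitions + 1L
        state <- -1L
      }
    }
    if (transitions >= 2) return("bistable")
  }

  "quiescent"
}

#' Characterise responses to square-wave stimulation
#'
#' For each response channel, estimates the off-phase baseline (mean and
#' variance, excluding a window after every stimulus transition), the mean
#' input-output difference `delta_v_mV` (mean stimulus amplitude minus the
#' mean evoked displacement above baseline), the onset latency (time from the
#' stimulus rising edge to 10\% of the evoked change), and the recovery time
#' (time after the falling edge for the response to come back within 10\% of
#' the evoked amplitude of baseline). Latency and recovery are medians over
#' stimulation cycles, reported in ms.
#'
#' @param stimulus Tibble `time_s`, `stim_mV` (square wave).
#' @param responses Multichannel trace tibble on the same time base.
#' @param settle_exclude_s Window excluded after each transition when
#'   averaging baseline and evoked levels.
#' @return Tibble, one row per channel: `channel`, `baseline_mean_mV`,
#'   `baseline_variance_mV2`, `delta_v_mV`, `latency_ms`, `recovery_ms`.
#' @export
stimulation_response <- function(stimulus, responses, settle_exclude_s = 0.05) {
  if (!isTRUE(all.equal(stimulus$time_s, responses$time_s))) {
    abort("stimulus and responses must share a time base.",
          class = "protoelec_format_error")
  }
  dt <- trace_dt(responses)
  s <- stimulus$stim_mV
  amp <- max(s) - min(s)
  if (amp == 0) {
    abort("stimulus has no transitions.", class = "protoelec_invalid_spec")
  }
  gate <- s > min(s) + amp / 2
  d <- diff(gate)
  on_edges <- which(d == 1) + 1   # first sample of the on phase
  off_edges <- which(d == -1) + 1 # first sample of the off phase
  if (length(on_edges) == 0) {
    abort("stimulus has no transitions.", class = "protoelec_invalid_spec")
  }
  excl_n <- ceiling(settle_exclude_s / dt)
  n <- length(s)
  settled <- rep(TRUE, n)
  # the recording start acts as a transition too (the response has not yet
  # risen/settled there), so exclude the first window as well
  for (e in sort(c(1L, on_edges, off_edges))) {
    settled[seq.int(e, min(n, e + excl_n))] <- FALSE
  }
  stim_on_mean <- mean(s[gate]) - mean(s[!gate])

  purrr::map_dfr(trace_channels(responses), function(ch) {
    v <- responses[[ch]]
    base_idx <- !gate & settled
    b_mean <- mean(v[base_idx])
    b_var <- var(v[base_idx])
    evoked <- mean(v[gate & settled]) - b_mean
    lat <- vapply(on_edges, function(e) {
      horizon <- seq.int(e, min(n, e + max(1, round(0.5 / dt))))
      hit <- which(abs(v[horizon] - b_mean) >= 0.1 * abs(evoked))[1]
      if (is.na(hit)) NA_real_ else (hit - 1) * dt
    }, numeric(1))
    lat_med <- median(lat, na.rm = TRUE)
    rec <- vapply(off_edges, function(e) {
      horizon <- seq.int(e, min(n, e + max(1, round(0.5 / dt))))
      hit <- which(abs(v[horizon] - b_mean) <= 0.1 * abs(evoked))[1]
      # decay time proper: drop the propagation latency before the falling
      # edge reaches the channel
      if (is.na(hit)) NA_real_ else (hit - 1) * dt - lat_med
    }, numeric(1))
    tibble(
      channel = ch,
      baseline_mean_mV = b_mean,
      baseline_variance_mV2 = b_var,
      delta_v_mV = stim_on_mean - evoked,
      latency_ms = lat_med * 1000,
      recovery_ms = median(rec, na.rm = TRUE) * 1000
    )
  })
}

#' Memory-effect analysis of repeated current-voltage sweep cycles
#'
#' Computes each cycle's mean resistance (sample-wise V/I restricted to
#' \eqn{|V|} above a dead-band, avoiding the divide-by-zero region near 0 V)
#' and the Pearson correlation between cycle number and mean resistance,
#' \deqn{r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'                {\sqrt{\sum_i (x_i - \bar x)^2}\sqrt{\sum_i (y_i - \bar y)^2}},}
#' the standard memory-effect statistic for cycling experiments. `r` is
#' defined as 0 when either variance is zero.
#'
#' @param sweeps Tibble with columns `cycle`, `time_s`, `v_V`, `i_A` (long
#'   format, as produced by [gen_iv_sweeps()]).
#' @param dead_band_V Exclude samples with `|v_V|` below this.
#' @return List with `per_cycle` (tibble `cycle`, `r_mean_ohm`, `r_sd_ohm`)
#'   and `pearson_r` (scalar).
#' @export
iv_cycle_analysis <- function(sweeps, dead_band_V = 0.25) {
  need <- c("cycle", "v_V", "i_A")
  if (!all(need %in% names(sweeps))) {
    abort("sweeps need columns cycle, v_V, i_A.", class = "protoelec_format_error")
  }
  if (length(unique(sweeps$cycle)) < 2) {
    abort("need at least 2 cycles.", class = "protoelec_insufficient_data")
  }
  kept <- dplyr::filter(sweeps, abs(.data$v_V) >= dead_band_V)
  if (nrow(kept) == 0) {
    abort("all samples fall inside the dead-band.",
          class = "protoelec_insufficient_data")
  }
  per_cycle <- kept |>
    dplyr::mutate(r_ohm = .data$v_V / .data$i_A) |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(r_mean_ohm = mean(.data$r_ohm),
                     r_sd_ohm = sd(.data$r_ohm), .groups = "drop") |>
    dplyr::arrange(.data$cycle)
  x <- per_cycle$cycle
  y <- per_cycle$r_mean_ohm
  r <- if (sd(x) == 0 || sd(y) == 0 || !all(is.finite(y))) 0 else cor(x, y)
  list(per_cycle = per_cycle, pearson_r = r)
}

#' Plot a multichannel trace
#'
#' @param trace Multichannel trace tibble.
#' @param channels Optional subset of channel names.
#' @return A ggplot of membrane potential against time, one facet per channel.
#' @export
plot_trace <- function(trace, channels = NULL) {
  chs <- channels %||% trace_channels(trace)
  long <- tidyr::pivot_longer(trace[, c("time_s", chs)], -"time_s",
                              names_to = "channel", values_to = "v_mV")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$v_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "membrane potential (mV)")
}
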