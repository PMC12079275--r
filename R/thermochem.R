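# Spectral helpers ----------------------------------------------------------

# Hann-windowed, linearly detrended, 4x zero-padded periodogram.
# Returns freq (Hz) and power, excluding the zero frequency.
periodogram <- function(x, dt_s, pad_factor = 4) {
  n <- length(x)
  x <- linear_detrend(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  xw <- x * w
  nfft <- nextn(pad_factor * n, 2)
  sp <- fft(c(xw, rep(0, nfft - n)))
  half <- seq_len(floor(nfft / 2))
  list(freq = (half) / (nfft * dt_s),
       power = Mod(sp[half + 1])^2)
}

#' Dominant oscillation period of a series
#'
#' Period at the maximum of the Hann-windowed, linearly detrended, 4x
#' zero-padded periodogram, refined by parabolic interpolation of log-power
#' around the peak. A peak is only accepted when it carries at least
#' `min_peak_frac` of the total detrended power; otherwise the series is
#' treated as having no dominant oscillation.
#'
#' @param x Numeric series (at least 64 samples).
#' @param dt_s Sampling interval in seconds.
#' @param min_peak_frac Minimum fraction of total power in the peak bin.
#' @return Dominant period in seconds.
#' @examples
#' t <- seq(0, 4 * 3600, by = 10)
#' dominant_period(sin(2 * pi * t / 3600), dt_s = 10) # ~3600
#' @export
dominant_period <- function(x, dt_s, min_peak_frac = 0.05) {
  if (length(x) < 64) {
    abort("need at least 64 samples.", class = "protoelec_insufficient_data")
  }
  check_positive(dt_s, "dt_s")
  if (sd(x) == 0) {
    abort("series is constant: no oscillation peak.",
          class = "protoelec_no_peak")
  }
  pg <- periodogram(x, dt_s)
  k <- which.max(pg$power)
  if (pg$power[k] < min_peak_frac * sum(pg$power)) {
    abort("no dominant spectral peak (power too diffuse).",
          class = "protoelec_no_peak")
  }
  f <- pg$freq[k]
  if (k > 1 && k < length(pg$power)) {
    lp <- log(pg$power[(k - 1):(k + 1)] + .Machine$double.xmin)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / denom
      df <- pg$freq[2] - pg$freq[1]
      f <- f + delta * df
    }
  }
  1 / f
}

# Exact normalised cross-correlation over the overlapping window at each
# candidate lag: r(k) = Pearson cor of (y_{t+k}, x_t) over the n - |k|
# overlapping pairs. The cross sums come from an FFT linear correlation and
# the per-lag means/variances from prefix sums, so a pure shift of a periodic
# series scores exactly 1 at the true lag.
cross_correlation_exact <- function(x, y, max_lag) {
  n <- length(x)
  nfft <- nextn(2 * n, 2)
  fx <- fft(c(x, rep(0, nfft - n)))
  fy <- fft(c(y, rep(0, nfft - n)))
  cc <- Re(fft(fy * Conj(fx), inverse = TRUE)) / nfft
  # cc[k + 1] = sum_t x_t y_{t+k} for k >= 0; cc[nfft + 1 - k] for k < 0
  ks <- (-max_lag):max_lag
  sxy <- cc[ifelse(ks >= 0, ks + 1, nfft + 1 + ks)]
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  sum_range <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  r <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    m <- n - abs(k)
    if (k >= 0) {
      sx <- sum_range(cx, 1, m); sxx <- sum_range(cx2, 1, m)
      sy <- sum_range(cy, k + 1, n); syy <- sum_range(cy2, k + 1, n)
    } else {
      sx <- sum_range(cx, -k + 1, n); sxx <- sum_range(cx2, -k + 1, n)
      sy <- sum_range(cy, 1, m); syy <- sum_range(cy2, 1, m)
    }
    num <- sxy[i] - sx * sy / m
    den <- sqrt(max(sxx - sx^2 / m, 0) * max(syy - sy^2 / m, 0))
    if (den <= 0) 0 else num / den
  }, numeric(1))
  list(lag = ks, r = r)
}

#' Phase lag between temperature and pH oscillations
#'
#' Lag (in seconds) at the maximum of the exact normalised cross-correlation,
#' searched within plus or minus half the shared dominant period (a lag of a
#' full half-period is indistinguishable from its alias for near-periodic
#' signals, so the search is restricted to the identifiable range). Each
#' candidate lag uses the exact Pearson correlation of the overlapping
#' samples, which demeans per window, so a pure shift is recovered to the
#' sample; no global detrend is applied here (it would perturb the two series
#' asymmetrically). Positive values mean the pH series lags the temperature
#' series (pH adjustments occur after temperature swings).
#'
#' @param env Tibble with columns `time_s`, `temperature_C`, `pH` (uniform
#'   time base), as produced by [gen_env_series()].
#' @return Lag in seconds (an integer multiple of the sampling interval).
#' @export
phase_lag <- function(env) {
  dt <- trace_dt(env)
  x <- env$temperature_C
  y <- env$pH
  if (sd(x) == 0 || sd(y) == 0) {
    abort("both series must be non-constant.", class = "protoelec_invalid_spec")
  }
  best_lag(x, y, dt)$lag_samples * dt
}

# Peak of the exact cross-correlation within half the dominant period.
best_lag <- function(x, y, dt) {
  per <- tryCatch(dominant_period(x, dt), error = function(e) length(x) * dt / 4)
  max_lag <- min(length(x) - 2, max(1, round(per / dt / 2)))
  cc <- cross_correlation_exact(x, y, max_lag)
  i <- which.max(cc$r)
  list(lag_samples = cc$lag[i], r = cc$r[i])
}

#' Temperature-pH coupling coefficient
#'
#' Magnitude-squared coherence of the detrended temperature and pH series at
#' their shared dominant frequency, estimated by a smoothed cross-periodogram
#' ([stats::spec.pgram()] with modified Daniell smoothing). Because the pH
#' response trails the temperature swing, the two series are first aligned by
#' the cross-correlation phase lag (otherwise the delay's linearly rotating
#' cross-phase decoheres the frequency-smoothed estimate). Alignment is only
#' applied when the cross-correlation peak is substantial
#' (`align_threshold`); for unrelated series the best-lag shift is a chance
#' alignment that would bias the null upwards. The value lies in [0, 1]: 1
#' for a noiseless linear (amplitude-scaled, offset, delayed) relation at the
#' dominant frequency, near 0 for independent signals.
#'
#' @param env Tibble with columns `time_s`, `temperature_C`, `pH`.
#' @param spans Daniell smoother spans passed to [stats::spec.pgram()].
#' @param align Align the series by the cross-correlation lag first.
#' @param align_threshold Minimum cross-correlation peak for alignment.
#' @return Coupling coefficient kappa in [0, 1].
#' @export
coupling_coefficient <- function(env, spans = 11, align = TRUE,
                                 align_threshold = 0.2) {
  dt <- trace_dt(env)
  x <- env$temperature_C
  y <- env$pH
  if (sd(x) == 0 || sd(y) == 0) {
    abort("both series must be non-constant.", class = "protoelec_invalid_spec")
  }
  if (align) {
    bl <- best_lag(x, y, dt)
    k <- bl$lag_samples
    n <- length(x)
    if (bl$r > align_threshold) {
      if (k > 0 && k < n - 64) {
        x <- x[seq_len(n - k)]
        y <- y[(k + 1):n]
      } else if (k < 0 && -k < n - 64) {
        y <- y[seq_len(n + k)]
        x <- x[(-k + 1):n]
      }
    }
  }
  xd <- linear_detrend(x)
  yd <- linear_detrend(y)
  sp <- stats::spec.pgram(cbind(xd, yd), spans = spans, taper = 0.1,
                          detrend = FALSE, demean = TRUE, plot = FALSE)
  # dominant shared frequency: peak of the summed (normalised) auto-spectra
  px <- sp$spec[, 1] / sum(sp$spec[, 1])
  py <- sp$spec[, 2] / sum(sp$spec[, 2])
  k <- which.max(px + py)
  kappa <- sp$coh[k]
  min(max(kappa, 0), 1)
}

#' Normalised autocorrelation at a requested lag
#'
#' @param x Numeric series.
#' @param lag_s Lag in seconds (rounded to the nearest sample; must be within
#'   the series span).
#' @param dt_s Sampling interval in seconds.
#' @param demean Subtract the mean before correlating (default TRUE).
#' @return Autocorrelation r(lag), with r(0) = 1.
#' @export
autocorrelation <- function(x, lag_s, dt_s, demean = TRUE) {
  check_positive(dt_s, "dt_s")
  k <- round(lag_s / dt_s)
  n <- length(x)
  if (k < 0 || k >= n) {
    abort("lag out of range for the series.", class = "protoelec_domain_error")
  }
  if (k == 0) return(1)
  a <- stats::acf(x, lag.max = k, plot = FALSE, demean = demean)
  as.numeric(a$acf[k + 1])
}

#' Arrhenius protonation rate
#'
#' Temperature dependence of the protonation/deprotonation kinetics,
#' \deqn{k(T) = k_0 \exp\left(-\frac{E_a}{R T}\right)}
#' with \eqn{T} in kelvin and the gas constant \eqn{R = 8.314462618}
#' J/(mol K). The published activation energy for these networks is about
#' 29.3 kJ/mol.
#'
#' @param temperature_C Temperature(s) in degrees Celsius (above -273.15).
#' @param ea_kJ_mol Activation energy in kJ/mol (non-negative).
#' @param k0 Pre-exponential factor in s^-1.
#' @return Rate(s) in s^-1.
#' @examples
#' arrhenius_rate(25, ea_kJ_mol = 29.3) / arrhenius_rate(16, ea_kJ_mol = 29.3)
#' @export
arrhenius_rate <- function(temperature_C, ea_kJ_mol = 29.3, k0 = 1) {
  if (any(temperature_C <= -273.15)) {
    abort("temperature must be above absolute zero.",
          class = "protoelec_domain_error")
  }
  check_nonneg(ea_kJ_mol, "ea_kJ_mol")
  check_positive(k0, "k0")
  R_gas <- 8.314462618 # J / (mol K)
  k0 * exp(-ea_kJ_mol * 1000 / (R_gas * (temperature_C + 273.15)))
}

#' Full temperature-pH coupling report
#'
#' Convenience wrapper computing both dominant periods, the phase lag, the
#' coupling coefficient and an autocorrelation curve for the pH series.
#'
#' @param env Tibble with `time_s`, `temperature_C`, `pH`.
#' @param acf_max_lag_s Largest autocorrelation lag (seconds).
#' @return List with `period_temperature_s`, `period_ph_s`, `phase_lag_s`,
#'   `coupling`, and `acf` (tibble `lag_s`, `r`).
#' @export
env_coupling <- function(env, acf_max_lag_s = 1000) {
  dt <- trace_dt(env)
  lags <- seq(0, acf_max_lag_s, by = dt)
  list(
    period_temperature_s = dominant_period(env$temperature_C, dt),
    period_ph_s = dominant_period(env$pH, dt),
    phase_lag_s = phase_lag(env),
    coupling = coupling_coefficient(env),
    acf = tibble(lag_s = lags,
                 r = vapply(lags, function(l) autocorrelation(env$pH, l, dt),
                            numeric(1)))
  )
}
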