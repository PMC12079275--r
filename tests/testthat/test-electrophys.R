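make_trace <- function(v, dt = 0.4) {
  tibble::tibble(time_s = (seq_along(v) - 1) * dt, ch1 = v)
}

test_that("spike detection finds planted spikes and nothing on flat traces", {
  expect_equal(nrow(detect_spikes(make_trace(rep(3, 500)), "ch1")), 0)

  # 10 identical spikes, no noise: all found at the planted samples
  spec <- spiking_trace_spec(isi_mean_s = 50, isi_cv = 0, noise_sd_mV = 0,
                             spike_amp_sd_mV = 0, duration_s = 501, seed = 1)
  tr <- gen_spiking_trace(spec)
  sp <- detect_spikes(tr, "ch1")
  expect_true(nrow(sp) %in% c(9, 10))
  expect_true(all(abs(sp$time_s - seq(50, by = 50,
                                      length.out = nrow(sp))) <= 0.4))
  expect_equal(sp$amplitude_mV, rep(25.3, nrow(sp)), tolerance = 0.01)

  expect_error(detect_spikes(tr, "nope"), class = "protoelec_key_error")
})

test_that("detection counts equal a brute-force all-maxima-then-filter oracle", {
  for (s in 1:6) {
    v <- withr::with_seed(s, {
      base <- rnorm(1000, 0, 2)
      for (k in sample(50:950, 8)) base[k] <- base[k] + runif(1, 6, 30)
      base
    })
    tr <- make_trace(v)
    got <- nrow(detect_spikes(tr, "ch1"))
    want <- oracle_detect_count(v, 0.4, 5, 10)
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("spike detection is translation invariant", {
  spec <- spiking_trace_spec(duration_s = 3000, seed = 12)
  tr <- gen_spiking_trace(spec)
  tr2 <- tr
  tr2$ch1 <- tr2$ch1 + 500
  a <- detect_spikes(tr, "ch1")
  b <- detect_spikes(tr2, "ch1")
  expect_equal(a$index, b$index)
  expect_equal(a$amplitude_mV, b$amplitude_mV, tolerance = 1e-12)
})

test_that("spike statistics summarise amplitudes and periods per channel", {
  # two spikes 52.4 s apart -> period mean 52.4
  v <- rep(0, 1000)
  v[100] <- 20
  v[100 + 131] <- 20 # 131 samples * 0.4 s = 52.4 s
  st <- spike_stats(make_trace(v))
  expect_equal(st$n_spikes, 2)
  expect_equal(st$period_mean_s, 52.4, tolerance = 1e-12)

  # amplitudes {1,2,3} (planted above threshold): median 2, mean 2, sample sd 1
  v2 <- rep(0, 2000)
  v2[c(300, 600, 900)] <- c(11, 12, 13)
  st2 <- spike_stats(make_trace(v2), min_prominence_mV = 5)
  expect_equal(st2$amp_median_mV - 11, 1)
  expect_equal(st2$amp_mean_mV, 12)
  expect_equal(st2$amp_sd_mV, 1)
  expect_equal(st2$amp_max_mV, 13)

  # empty channel yields an n_spikes = 0 row, not an error
  st3 <- spike_stats(make_trace(rep(0, 500)))
  expect_equal(st3$n_spikes, 0)
  expect_true(is.na(st3$amp_mean_mV))
})

test_that("period statistics ignore amplitude rescaling", {
  tr <- gen_spiking_trace(spiking_trace_spec(duration_s = 5000, seed = 3))
  st1 <- spike_stats(tr)
  tr$ch1 <- tr$ch1 * 3
  st2 <- spike_stats(tr, min_prominence_mV = 15)
  expect_equal(st2$period_mean_s, st1$period_mean_s, tolerance = 1e-12)
  expect_equal(st2$n_spikes, st1$n_spikes)
})

test_that("long synthetic regular-spiking traces recover their planted statistics", {
  # noisy trace and its noiseless twin share ISI and amplitude draws (the
  # noise is drawn after them), so the twin's statistics are the planted truth
  for (s in c(1, 2, 3)) {
    noisy <- gen_spiking_trace(spiking_trace_spec(seed = s, duration_s = 8000))
    clean <- gen_spiking_trace(spiking_trace_spec(seed = s, duration_s = 8000,
                                                  noise_sd_mV = 0))
    stn <- spike_stats(noisy)
    stc <- spike_stats(clean)
    expect_equal(stn$n_spikes, stc$n_spikes)
    expect_lt(abs(stn$amp_mean_mV - stc$amp_mean_mV), 0.5)
    expect_lt(abs(stn$period_mean_s - stc$period_mean_s), 0.5)
  }
})

test_that("recovery holds across configurations spanning the recorded ranges", {
  # amplitudes ~10-40 mV and periods tens to hundreds of seconds, as in the
  # published per-channel summaries; noisy vs noiseless-twin comparison
  cfgs <- expand.grid(amp = c(10, 20, 30, 40), isi = c(40, 80, 150, 300, 600))
  for (i in seq_len(nrow(cfgs))) {
    spec <- spiking_trace_spec(spike_amp_mean_mV = cfgs$amp[i],
                               spike_amp_sd_mV = 0.15 * cfgs$amp[i],
                               isi_mean_s = cfgs$isi[i],
                               duration_s = max(6000, 40 * cfgs$isi[i]),
                               seed = 100 + i)
    noisy <- gen_spiking_trace(spec)
    spec0 <- spec; spec0$noise_sd_mV <- 0
    clean <- gen_spiking_trace(spec0)
    stn <- spike_stats(noisy)
    stc <- spike_stats(clean)
    expect_gt(stn$n_spikes, 10)
    expect_lt(abs(stn$amp_mean_mV - stc$amp_mean_mV), 0.6)
    expect_lt(abs(stn$period_mean_s - stc$period_mean_s),
              0.01 * cfgs$isi[i] + 0.5)
  }
})

test_that("dynamics classification labels the four regimes", {
  expect_equal(classify_dynamics(gen_spiking_trace(
    spiking_trace_spec(duration_s = 3000, seed = 2)), "ch1"),
    "regular_spiking")
  expect_equal(classify_dynamics(gen_multiphasic_trace(
    multiphasic_profile("plateau")), "ch1"), "plateau_class2")
  expect_equal(classify_dynamics(gen_multiphasic_trace(
    multiphasic_profile("bistable"), noise_sd_mV = 2, seed = 3), "ch1"),
    "bistable")
  expect_equal(classify_dynamics(make_trace(rep(7, 500)), "ch1"), "quiescent")
  expect_error(classify_dynamics(make_trace(rep(0, 50)), "ch1"),
               class = "protoelec_insufficient_data")
})

test_that("multiphasic generator hits its targets exactly without noise", {
  # single constant phase at 0 -> flat zero trace
  flat <- gen_multiphasic_trace(data.frame(duration_s = 100, target_mV = 0,
                                           shape = "constant"))
  expect_equal(flat$ch1, rep(0, nrow(flat)))

  # plateau profile: plateau segment mean is the target, final level settles
  tr <- gen_multiphasic_trace(multiphasic_profile("plateau"))
  prof <- multiphasic_profile("plateau")
  n1 <- floor(prof$duration_s[1] / 0.4)
  n2 <- floor(prof$duration_s[2] / 0.4)
  expect_equal(mean(tr$ch1[(n1 + 1):(n1 + n2)]), 40, tolerance = 1e-12)
  expect_equal(tail(tr$ch1, 1), -20, tolerance = 0.02)
  # depolarisation ramp slope ~ 8 mV/min
  slope <- (tr$ch1[n1] - tr$ch1[1]) / (prof$duration_s[1] / 60)
  expect_equal(slope, 8, tolerance = 0.05)

  expect_error(gen_multiphasic_trace(data.frame()),
               class = "protoelec_invalid_spec")
})

test_that("stimulation response recovers the planted session parameters", {
  ss <- gen_stimulation_session(stimulation_spec())
  resp <- stimulation_response(ss$stimulus, ss$response)
  cfg <- stimulation_spec()$channels

  expect_equal(resp$channel, cfg$channel)
  # baselines within 0.5 mV (channel C: -6.22 published)
  expect_true(all(abs(resp$baseline_mean_mV - cfg$baseline_mean_mV) < 0.5))
  # input-output differences within 1 mV of the configured attenuations
  expect_true(all(abs(resp$delta_v_mV - cfg$attenuation_mV) < 1))
  # latencies and recoveries to within one sample (1 ms) plus rounding
  expect_true(all(abs(resp$latency_ms - cfg$latency_ms) <= 1))
  expect_true(all(abs(resp$recovery_ms - cfg$recovery_ms) <= 1))
  # baseline variance in the published 0.66-3.12 mV^2 range
  expect_true(all(resp$baseline_variance_mV2 > 0.3 &
                  resp$baseline_variance_mV2 < 4))
})

test_that("stimulation edge cases behave as constructed", {
  # attenuation equal to the stimulus amplitude: response is pure baseline
  ch <- tibble::tibble(channel = "chA", baseline_mean_mV = -10,
                       baseline_sd_mV = 0, attenuation_mV = 1000,
                       latency_ms = 5, recovery_ms = 10)
  ss <- gen_stimulation_session(stimulation_spec(channels = ch))
  resp <- stimulation_response(ss$stimulus, ss$response)
  expect_equal(resp$delta_v_mV, 1000, tolerance = 1e-9)
  expect_equal(resp$baseline_mean_mV, -10, tolerance = 1e-9)
  expect_equal(resp$baseline_variance_mV2, 0, tolerance = 1e-12)

  # planted 5 ms latency recovered within 1 ms
  ch2 <- ch; ch2$attenuation_mV <- 300
  ss2 <- gen_stimulation_session(stimulation_spec(channels = ch2))
  resp2 <- stimulation_response(ss2$stimulus, ss2$response)
  expect_lte(abs(resp2$latency_ms - 5), 1)

  # stimulus with no transitions rejected
  flat_stim <- ss$stimulus
  flat_stim$stim_mV <- 0
  expect_error(stimulation_response(flat_stim, ss$response),
               class = "protoelec_invalid_spec")
  # too-coarse sampling for the latency
  expect_error(stimulation_spec(channels = ch, dt_s = 0.01),
               class = "protoelec_invalid_spec")
})

test_that("iv cycle analysis matches Pearson oracles and handles edge cases", {
  # monotone drift -> r = 1; reversed -> r = -1
  up <- gen_iv_sweeps(1000, drift_per_cycle = 5, n_cycles = 20)
  expect_equal(iv_cycle_analysis(up)$pearson_r, 1, tolerance = 1e-9)
  down <- gen_iv_sweeps(1000, drift_per_cycle = -5, n_cycles = 20)
  expect_equal(iv_cycle_analysis(down)$pearson_r, -1, tolerance = 1e-9)
  # constant resistance: r defined as 0
  flat <- gen_iv_sweeps(1000, n_cycles = 10)
  expect_equal(iv_cycle_analysis(flat)$pearson_r, 0)

  # small-sample oracle agreement
  x <- c(1, 2, 3, 4)
  y <- c(2.0, 2.1, 1.9, 2.2)
  expect_equal(cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)

  # analysis r equals the oracle applied to its own per-cycle means
  sw <- gen_iv_sweeps(2e5, drift_per_cycle = 100, r_noise_sd = 3950,
                      hysteresis_width = 2e-6, seed = 1)
  res <- iv_cycle_analysis(sw)
  expect_equal(res$pearson_r,
               oracle_pearson(res$per_cycle$cycle, res$per_cycle$r_mean_ohm),
               tolerance = 1e-12)

  expect_error(iv_cycle_analysis(gen_iv_sweeps(100, n_cycles = 1)),
               class = "protoelec_insufficient_data")
  expect_error(iv_cycle_analysis(sw, dead_band_V = 100),
               class = "protoelec_insufficient_data")
})

test_that("the memory-effect condition reproduces a weak positive correlation", {
  # drift/noise chosen so the population correlation is ~0.35 over 50 cycles;
  # a single 50-cycle experiment has sampling sd ~0.13, so average over seeds
  rr <- vapply(1:8, function(s) {
    sw <- gen_iv_sweeps(2e5, drift_per_cycle = 100, r_noise_sd = 3950,
                        hysteresis_width = 2e-6, seed = s)
    iv_cycle_analysis(sw)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rr) - 0.35), 0.1)
  expect_true(all(rr >= -1 & rr <= 1))
})

test_that("pearson r stays in [-1, 1] and is affine invariant under fuzzing", {
  for (s in 1:10) {
    xy <- withr::with_seed(s, list(x = rnorm(30), y = rnorm(30)))
    r <- cor(xy$x, xy$y)
    expect_true(r >= -1 && r <= 1)
    expect_equal(cor(2 * xy$x + 3, -1 * xy$y + 7), -r, tolerance = 1e-12)
    expect_equal(r, oracle_pearson(xy$x, xy$y), tolerance = 1e-12)
  }
})
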