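freqs_default <- 10^seq(-4, 5, length.out = 60)

test_that("chi-squared matches an elementwise-loop oracle and scales quadratically", {
  m <- build_named_circuit("actin")
  sp <- gen_impedance_spectrum(m, freqs_default, noise_frac = 0.05, seed = 2)
  got <- chi_squared(sp, m)
  want <- oracle_chi_squared_raw(sp, m)
  expect_equal(got, want, tolerance = 1e-12)

  # zero for the generating model without noise
  sp0 <- gen_impedance_spectrum(m, freqs_default)
  expect_equal(chi_squared(sp0, m), 0, tolerance = 1e-25)

  # doubling all residuals quadruples the statistic
  sp2 <- sp
  zm <- circuit_impedance(m, sp$freq_hz)
  sp2$z_real_ohm <- zm$z_real_ohm + 2 * (sp$z_real_ohm - zm$z_real_ohm)
  sp2$z_imag_ohm <- zm$z_imag_ohm + 2 * (sp$z_imag_ohm - zm$z_imag_ohm)
  # weights follow the observed spectrum, so compare against the raw oracle
  expect_equal(chi_squared(sp2, m), oracle_chi_squared_raw(sp2, m),
               tolerance = 1e-12)
  sp2u <- sp2
  expect_equal(chi_squared(sp2, m, weighting = "unit"),
               4 * chi_squared(sp, m, weighting = "unit"), tolerance = 1e-12)

  expect_error(chi_squared(sp[0, ], m), class = "protoelec_insufficient_data")
})

test_that("noiseless round trips recover the published parameters", {
  # jittered initial values, well away from the optimum
  for (nm in c("actin", "mixture")) {
    m <- build_named_circuit(nm)
    truth <- true_params_flat(nm)
    sp <- gen_impedance_spectrum(m, freqs_default)
    init <- withr::with_seed(11, truth * exp(runif(length(truth), -1, 1) * log(3)))
    fit <- fit_circuit(sp, m, initial = init)
    expect_true(fit$converged, info = nm)
    expect_lt(fit$chi_squared, 1e-8)
    expect_true(all(abs(fit$params - truth) / truth < 1e-3), info = nm)
  }

  # proteinoid: C1 sits at the published lower fitting limit (1e-12 F), which
  # makes R2||C1 a pure resistor in-band; R1 and R2 are then only jointly
  # identifiable, so the recovery check applies to W1, the O element, and the
  # series total R1 + R2.
  m <- build_named_circuit("proteinoid")
  truth <- true_params_flat("proteinoid")
  sp <- gen_impedance_spectrum(m, freqs_default)
  init <- withr::with_seed(11, truth * exp(runif(length(truth), -1, 1) * log(3)))
  fit <- fit_circuit(sp, m, initial = init)
  expect_lt(fit$chi_squared, 1e-8)
  ident <- c("n2.warburg.w", "n3.o_element.y0", "n3.o_element.b")
  expect_true(all(abs(fit$params[ident] - truth[ident]) / truth[ident] < 1e-3))
  r_tot_hat <- fit$params[["n1.resistor.r"]] + fit$params[["n4.p1.resistor.r"]]
  r_tot <- truth[["n1.resistor.r"]] + truth[["n4.p1.resistor.r"]]
  expect_lt(abs(r_tot_hat - r_tot) / r_tot, 1e-3)
})

test_that("1% multiplicative noise leaves well-determined parameters within 5%", {
  # a parameter is treated as well-determined when its curvature uncertainty
  # is below 2.5% (two standard errors inside the 5% band)
  for (nm in c("actin", "proteinoid", "mixture")) {
    m <- build_named_circuit(nm)
    truth <- true_params_flat(nm)
    sp <- gen_impedance_spectrum(m, freqs_default, noise_frac = 0.01, seed = 5)
    fit <- fit_circuit(sp, m)
    keep <- !is.na(fit$rel_uncertainty_pct) & fit$rel_uncertainty_pct < 2.5
    expect_gt(sum(keep), 1)
    expect_true(all(abs(fit$params[keep] - truth[keep]) / truth[keep] < 0.05),
                info = nm)
  }
})

test_that("fit never worsens the initial model and ignores frequency order", {
  m <- build_named_circuit("actin")
  truth <- true_params_flat("actin")
  sp <- gen_impedance_spectrum(m, freqs_default, noise_frac = 0.02, seed = 9)
  init <- truth * 1.5
  fit <- fit_circuit(sp, m, initial = init, n_restarts = 0)
  chi_init <- chi_squared(sp, protoelec:::circuit_set_params(m, init),
                          n_params = length(init))
  expect_lte(fit$chi_squared, chi_init)

  perm <- withr::with_seed(4, sample(nrow(sp)))
  fit_perm <- fit_circuit(sp[perm, ], m)
  fit_ref <- fit_circuit(sp, m)
  expect_equal(fit_perm$params, fit_ref$params, tolerance = 1e-6)
})

test_that("starting at the optimum converges immediately", {
  m <- build_named_circuit("mixture")
  sp <- gen_impedance_spectrum(m, freqs_default)
  fit <- fit_circuit(sp, m, n_restarts = 0)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 5)
})

test_that("bounded parameters pin at their bound and are flagged", {
  # a bound placed inside the optimum: the series resistance of the actin
  # model is capped below its true 143.3 ohm, so the fit must clip and flag
  m <- build_named_circuit("actin")
  sp <- gen_impedance_spectrum(m, freqs_default)
  fit <- fit_circuit(sp, m, upper = c(n3.resistor.r = 100), n_restarts = 0)
  expect_equal(fit$params[["n3.resistor.r"]], 100, tolerance = 1e-6)
  expect_true(fit$at_bound[["n3.resistor.r"]])
})

test_that("degenerate spectra are rejected", {
  m <- build_named_circuit("actin")
  sp <- gen_impedance_spectrum(m, c(1, 10))
  expect_error(fit_circuit(sp, m), class = "protoelec_insufficient_data")
})

test_that("nyquist summary reports the real-axis span and capacitive peak", {
  rsp <- circuit_impedance(circuit_model(elem_resistor(50)), c(0.1, 1, 10))
  ns <- nyquist_summary(rsp)
  expect_equal(ns$z_real_min, 50)
  expect_equal(ns$z_real_max, 50)
  expect_equal(ns$z_imag_peak, 0)

  # actin model over the measured band: real part spans ~[0.15, 1.03] kOhm
  sp <- circuit_impedance(build_named_circuit("actin"),
                          10^seq(-4, 5, length.out = 200))
  ns2 <- nyquist_summary(sp)
  expect_equal(ns2$z_real_min, 150, tolerance = 0.03)
  expect_equal(ns2$z_real_max, 1030, tolerance = 0.03)

  # Warburg divergence: proteinoid real part grows towards low frequency but
  # stays finite at the measurement cutoff
  spp <- circuit_impedance(build_named_circuit("proteinoid"),
                           10^seq(-4, 5, length.out = 50))
  expect_equal(which.max(spp$z_real_ohm), 1)
  expect_true(is.finite(max(spp$z_real_ohm)))
})

test_that("tidy and glance expose the fit as tibbles", {
  m <- build_named_circuit("actin")
  sp <- gen_impedance_spectrum(m, freqs_default)
  fit <- fit_circuit(sp, m, n_restarts = 0)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "rel_uncertainty_pct", "at_bound"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$n_freq, length(freqs_default))
  expect_true(gl$converged)
})
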