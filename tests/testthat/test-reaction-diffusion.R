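test_that("initial state seeds the substrate in a central square", {
  st <- gs_init(100, seed_region_half_width = 5)
  expect_equal(sum(st$b == 1), 121)
  expect_equal(sum(st$a), 100^2)
  expect_equal(st$step_count, 0L)

  # deterministic without noise regardless of seed
  expect_identical(gs_init(50, seed = 1), gs_init(50, seed = 999))

  expect_error(gs_init(10, seed_region_half_width = 20),
               class = "protoelec_invalid_spec")
  expect_error(gs_init(2), class = "protoelec_invalid_spec")
})

test_that("the trivial steady state A=1, B=0 is exactly preserved", {
  st <- structure(list(a = matrix(1, 40, 40), b = matrix(0, 40, 40),
                       step_count = 0L), class = "gs_state")
  for (nm in c("actin", "proteinoid", "mixture")) {
    out <- gs_step(st, gs_params(compound = nm))
    expect_identical(out$a, st$a, info = nm)
    expect_identical(out$b, st$b, info = nm)
  }
})

test_that("one step equals a from-scratch double-loop oracle", {
  st <- gs_init(20, seed_region_half_width = 3, noise_amp = 0.01, seed = 4)
  p <- gs_params(compound = "actin")
  got <- gs_step(st, p)
  want <- oracle_gs_step(st$a, st$b, p)
  expect_equal(got$a, want$a, tolerance = 1e-12)
  expect_equal(got$b, want$b, tolerance = 1e-12)
})

test_that("uniform fields stay uniform (zero Laplacian) and the torus sums cancel", {
  st <- structure(list(a = matrix(0.5, 30, 30), b = matrix(0.25, 30, 30),
                       step_count = 0L), class = "gs_state")
  out <- gs_step(st, gs_params(d_a = 0.16, d_b = 0.06, feed = 0.0202,
                               kill = 0.06))
  expect_equal(max(out$a) - min(out$a), 0)
  expect_equal(max(out$b) - min(out$b), 0)

  lap <- protoelec:::laplacian_periodic
  expect_equal(max(abs(lap(matrix(3.7, 25, 25)))), 0)
  m <- withr::with_seed(2, matrix(rnorm(900), 30))
  expect_equal(sum(lap(m)), 0, tolerance = 1e-10)
})

test_that("published parameter sets develop patterns within 5000 steps", {
  finals <- lapply(c("actin", "proteinoid", "mixture"), function(nm) {
    gs_simulate(gs_params(compound = nm), n_steps = 5000,
                init = gs_init(100, 5))
  })
  for (f in finals) {
    pm <- pattern_metrics(f)
    expect_gt(pm$spatial_sd_b, 0.01)
    # numerical stability regression: fields stay bounded
    expect_true(all(f$a > -1e-6 & f$a < 1.5))
    expect_true(all(f$b > -1e-6 & f$b < 1.5))
  }
  # the actin and proteinoid patterns differ
  corr <- cor(as.vector(finals[[1]]$b), as.vector(finals[[2]]$b))
  expect_lt(corr, 0.99)
})

test_that("simulation is bit-reproducible and translation covariant", {
  a <- gs_simulate(gs_params(compound = "actin"), n_steps = 300,
                   init = gs_init(50, 4, noise_amp = 0.01, seed = 6))
  b <- gs_simulate(gs_params(compound = "actin"), n_steps = 300,
                   init = gs_init(50, 4, noise_amp = 0.01, seed = 6))
  expect_identical(a$b, b$b)

  # periodic boundaries: translating the initial condition translates the
  # final field identically
  init1 <- gs_init(40, 3)
  shift <- function(m, k) m[c((k + 1):nrow(m), 1:k), ]
  init2 <- init1
  init2$a <- shift(init1$a, 7)
  init2$b <- shift(init1$b, 7)
  f1 <- gs_simulate(gs_params(compound = "mixture"), n_steps = 200, init = init1)
  f2 <- gs_simulate(gs_params(compound = "mixture"), n_steps = 200, init = init2)
  expect_equal(shift(f1$b, 7), f2$b, tolerance = 1e-12)
})

test_that("instability and invalid parameters are reported, not silent", {
  expect_error(gs_params(d_a = 0.3), class = "protoelec_invalid_spec")
  expect_error(gs_params(feed = -0.01), class = "protoelec_invalid_spec")
  # a wildly unstable dt blows up with a named instability error
  st <- gs_init(30, 3)
  expect_error({
    s <- st
    for (i in 1:200) s <- gs_step(s, gs_params(compound = "actin"), dt = 50)
  }, class = "protoelec_instability")
})

test_that("capacitance modulation scales D_A, D_B, F and holds k fixed", {
  base <- gs_params(compound = "actin")
  # constant capacitance or beta = 0: schedule identical to base
  sched0 <- modulate_params(base, rep(2.5, 100), beta = 1, n_steps = 50)
  expect_true(all(sched0$d_a == base$d_a))
  expect_true(all(sched0$feed == base$feed))
  schedb <- modulate_params(base, runif(100, 1, 2), beta = 0, n_steps = 50)
  expect_true(all(schedb$d_b == base$d_b))

  # sinusoidal 10% swing with beta = 1 spans exactly +/-10% of base F
  cc <- 1 + 0.1 * sin(2 * pi * (0:999) / 200)
  sched <- modulate_params(base, cc, beta = 1, n_steps = 1000)
  expect_equal(max(sched$feed) / base$feed, 1.1, tolerance = 1e-3)
  expect_equal(min(sched$feed) / base$feed, 0.9, tolerance = 1e-3)
  expect_true(all(sched$kill == base$kill))

  # generated capacitance series feed the scheduler for any positive decay
  for (rate in c(0, 1e-4, 1e-3)) {
    cap <- gen_capacitance_series(1.5, decay_rate = rate,
                                  fluctuation_sd = 0.01, duration_s = 500,
                                  seed = 3)
    expect_no_error(modulate_params(base, cap, n_steps = 200))
  }

  expect_error(modulate_params(base, c(1, -1, 2)),
               class = "protoelec_domain_error")
  expect_error(modulate_params(base, c(0.01, 10), beta = 1),
               class = "protoelec_invalid_spec")
})

test_that("pattern metrics count spots like a flood-fill oracle", {
  # uniform field: no spots, zero sd
  uni <- structure(list(a = matrix(1, 20, 20), b = matrix(0.3, 20, 20),
                        step_count = 0L), class = "gs_state")
  pm <- pattern_metrics(uni)
  expect_equal(pm$spatial_sd_b, 0)
  expect_equal(pm$spot_count, 0)
  expect_equal(pm$mean_b, 0.3)

  # two disjoint high squares
  b <- matrix(0, 30, 30)
  b[3:6, 3:6] <- 1
  b[20:24, 18:22] <- 1
  two <- structure(list(a = matrix(1, 30, 30), b = b, step_count = 0L),
                   class = "gs_state")
  expect_equal(pattern_metrics(two)$spot_count, 2)

  # random binary fields against the recursive flood-fill oracle
  for (s in 1:5) {
    mask <- withr::with_seed(s, matrix(runif(400) > 0.65, 20))
    expect_equal(protoelec:::count_components(mask), oracle_components(mask),
                 info = paste("seed", s))
  }
})
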