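test_that("passive simulator matches the closed form when leak is zero", {
  cfg <- sim_config(seed = 1, noise_cv = 0,
                    time_grid = c(0, 1, 2, 5, 10, 20, 50, 100))
  tc <- simulate_passive_uptake(0.5, 0.1, leak = 0, v_internal = 7.49e-8,
                                cfg = cfg)
  truth <- attr(tc, "truth")
  analytic <- 0.5 * (1 - exp(-0.1 * truth$time_s))
  expect_equal(truth$c_in_mM, analytic, tolerance = 1e-8)
  # with leak the ODE matches the two-rate closed form
  tc2 <- simulate_passive_uptake(0.5, 0.1, leak = 0.05,
                                 v_internal = 7.49e-8, cfg = cfg)
  t2 <- attr(tc2, "truth")
  analytic2 <- 0.5 * 0.1 / 0.15 * (1 - exp(-0.15 * t2$time_s))
  expect_equal(t2$c_in_mM, analytic2, tolerance = 1e-8)
})

test_that("a passive mechanism never concentrates substrate", {
  set.seed(77)
  for (i in 1:10) {
    c_out <- runif(1, 0.1, 5)
    cfg <- sim_config(seed = i, noise_cv = 0,
                      time_grid = seq(0, 500, by = 20))
    tc <- simulate_passive_uptake(c_out, runif(1, 0.01, 1),
                                  leak = runif(1, 0, 0.1),
                                  v_internal = 7.49e-8, cfg = cfg)
    folds <- fold_accumulation(attr(tc, "truth")$c_in_mM, c_out)
    expect_true(all(folds <= 1 + 1e-6))
  }
})

test_that("coupled simulator saturates at the fold limit and reduces to passive", {
  cfg <- sim_config(seed = 2, noise_cv = 0, time_grid = c(0, 10, 50, 1000))
  tc <- simulate_coupled_uptake(0.0025, 150, 0.05, v_internal = 7.49e-8,
                                cfg = cfg)
  truth <- attr(tc, "truth")
  expect_equal(truth$c_in_mM[4], 150 * 0.0025, tolerance = 1e-8)
  # fold_limit 1 is the passive closed form
  tc1 <- simulate_coupled_uptake(0.5, 1, 0.1, v_internal = 7.49e-8, cfg = cfg)
  expect_equal(attr(tc1, "truth")$c_in_mM,
               0.5 * (1 - exp(-0.1 * cfg$time_grid)), tolerance = 1e-12)
})

test_that("simulators are bit-reproducible for a fixed seed", {
  cfg <- sim_config(seed = 123)
  expect_identical(simulate_passive_uptake(0.5, 0.1, v_internal = 7e-8,
                                           cfg = cfg),
                   simulate_passive_uptake(0.5, 0.1, v_internal = 7e-8,
                                           cfg = cfg))
  expect_identical(simulate_mm_rates(8.69, 100.4, cfg = cfg),
                   simulate_mm_rates(8.69, 100.4, cfg = cfg))
  expect_identical(simulate_displacement(1e-3, cfg = cfg),
                   simulate_displacement(1e-3, cfg = cfg))
  expect_identical(simulate_iv(92, cfg = cfg), simulate_iv(92, cfg = cfg))
  # ... and the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_mm_rates(8, 100, cfg = cfg))
  expect_identical(runif(1), before)
})

test_that("the noise model delivers the requested coefficient of variation", {
  cfg <- sim_config(seed = 4, noise_cv = 0.05, n_replicates = 2000,
                    time_grid = c(0, 10))
  d <- simulate_mm_rates(8.69, 100.4, grid = c(1, 10, 50), cfg = cfg)
  for (s in c(1, 10, 50)) {
    v <- d$rate[d$conc_mM == s]
    expect_equal(sd(v) / mean(v), 0.05, tolerance = 0.1)
  }
})

test_that("noisy realizations average back to the noise-free curve", {
  cv <- 0.05; n <- 1e4
  cfg <- sim_config(seed = 6, noise_cv = cv, n_replicates = n,
                    time_grid = c(0, 5, 15, 60))
  tc <- simulate_passive_uptake(0.5, 0.1, v_internal = 7.49e-8, cfg = cfg)
  truth <- attr(tc, "truth")
  m <- aggregate(value ~ time_s, data = tc, FUN = mean)
  for (j in seq_len(nrow(m))) {
    mu <- truth$amount_nmol[truth$time_s == m$time_s[j]]
    if (mu > 0)
      expect_lt(abs(m$value[j] - mu), 3 * cv * mu / sqrt(n) + 1e-12)
  }
})

test_that("passive kinetics alone cannot reproduce a concentrative peak", {
  # matching the observed 2.49 mM internal peak from 0.5 mM outside would
  # need ~5-fold accumulation; the passive ODE is bounded by c_out
  cfg <- sim_config(seed = 8, noise_cv = 0, time_grid = seq(0, 120, 5))
  tc <- simulate_passive_uptake(0.5, 10, v_internal = 7.49e-8, cfg = cfg)
  folds <- fold_accumulation(attr(tc, "truth")$c_in_mM, 0.5)
  expect_true(all(folds <= 1 + 1e-6))
})

test_that("the integrity option creates a peaked measured course", {
  cfg <- sim_config(seed = 9, noise_cv = 0, time_grid = seq(0, 120, 5))
  tc <- simulate_passive_uptake(0.5, 0.2, v_internal = 7.49e-8, cfg = cfg,
                                integrity_decay = 0.02, integrity_floor = 0.5)
  amt <- attr(tc, "truth")$amount_nmol
  ipk <- which.max(amt)
  expect_gt(ipk, 1)
  expect_lt(ipk, length(amt))
  expect_lt(amt[length(amt)], amt[ipk])
})

test_that("gated traces occupy n_channels + 1 discrete levels", {
  cfg <- sim_config(seed = 10, noise_cv = 0)
  iv <- simulate_iv(92, open_prob = 0.5, n_channels = 3,
                    voltages = c(80), cfg = cfg, return_trace = TRUE,
                    trace_n = 5000)
  tr <- attr(iv, "traces")[["80mV"]]
  lv <- sort(unique(round(tr, 9)))
  expect_length(lv, 4)
  expect_equal(diff(lv), rep(92e-3 * 80, 3), tolerance = 1e-9)
  # noise/gating off: exact ohmic table
  iv0 <- simulate_iv(92, cfg = cfg)
  expect_equal(iv0$current_pA, 0.092 * iv0$voltage_mV, tolerance = 1e-12)
})

test_that("a peak-free saturating mean approaches the leak steady state", {
  cfg <- sim_config(seed = 12, noise_cv = 0, time_grid = c(0, 10, 1e4))
  tc <- simulate_passive_uptake(1, 0.1, leak = 0.025, v_internal = 7e-8,
                                cfg = cfg)
  expect_equal(attr(tc, "truth")$c_in_mM[3], 1 * 0.1 / 0.125,
               tolerance = 1e-6)
})
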