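test_that("initial rate recovers an exact linear uptake slope", {
  a <- ref_assay(protein_mass = 1)
  tc <- uptake_time_course(0:5, 0.02 * (0:5))
  expect_equal(initial_rate(tc, a), 1.2, tolerance = 1e-12)
  # protein normalization: 4 ug protein quarters the specific rate
  a4 <- ref_assay(protein_mass = 4)
  expect_equal(initial_rate(tc, a4), 0.3, tolerance = 1e-12)
  # default 5-s window excludes later curvature
  tc2 <- uptake_time_course(c(0:5, 60), c(0.02 * (0:5), 0.01))
  expect_equal(initial_rate(tc2, a), 1.2, tolerance = 1e-12)
  expect_error(initial_rate(tc, ref_assay()), "protein_mass")
  expect_error(initial_rate(
    uptake_time_course(c(0, 60), c(0, 1)), a), "within")
})

test_that("initial rate on a saturating curve approximates the true slope", {
  # A(t) = A_inf (1 - exp(-k t)); for small k*t the secant slope is A_inf*k
  a_inf <- 2; k <- 0.005
  tt <- 0:5
  tc <- uptake_time_course(tt, a_inf * (1 - exp(-k * tt)))
  a <- ref_assay(protein_mass = 1)
  expect_equal(initial_rate(tc, a), a_inf * k * 60, tolerance = 0.02)
})

test_that("Michaelis-Menten fit recovers noise-free parameters exactly", {
  km <- 8.69; vmax <- 100.4
  s <- exp(seq(log(0.5), log(50), length.out = 8))
  fit <- fit_michaelis_menten(data.frame(conc_mM = s,
                                         rate = vmax * s / (km + s)))
  expect_true(fit$converged)
  expect_equal(fit$km, km, tolerance = 1e-6)
  expect_equal(fit$vmax, vmax, tolerance = 1e-6)
  # half-maximal velocity at S = Km is the definition of Km
  pred <- predict(fit$fit, newdata = data.frame(conc_mM = fit$km))
  expect_equal(pred, fit$vmax / 2, tolerance = 1e-8)
})

test_that("Michaelis-Menten fit is scale-equivariant in the rates", {
  km <- 5; vmax <- 40
  s <- c(0.5, 1, 2, 5, 10, 20, 50)
  v <- vmax * s / (km + s)
  f1 <- fit_michaelis_menten(data.frame(conc_mM = s, rate = v))
  f2 <- fit_michaelis_menten(data.frame(conc_mM = s, rate = 3.7 * v))
  expect_equal(f2$vmax, 3.7 * f1$vmax, tolerance = 1e-8)
  expect_equal(f2$km, f1$km, tolerance = 1e-8)
})

test_that("Km recovery from noisy simulated rates is accurate and unbiased", {
  km_true <- 8.69; vmax_true <- 100.4
  kms <- vapply(1:100, function(s) {
    d <- simulate_mm_rates(km_true, vmax_true,
                           cfg = sim_config(seed = s, noise_cv = 0.05))
    fit_michaelis_menten(d)$km
  }, 0)
  rel_err <- abs(kms - km_true) / km_true
  expect_lt(median(rel_err), 0.10)
  # estimator bias across the seeds stays small
  expect_lt(abs(mean(kms) - km_true) / km_true, 0.03)
})

test_that("the NLS optimum beats a brute-force parameter grid", {
  ss_of <- function(km, vmax, d) sum((d$rate - vmax * d$conc_mM /
                                        (km + d$conc_mM))^2)
  for (s in 1:5) {
    d <- simulate_mm_rates(8.69, 100.4,
                           cfg = sim_config(seed = s, noise_cv = 0.05))
    fit <- fit_michaelis_menten(d)
    grid <- expand.grid(km = exp(seq(log(2), log(30), length.out = 60)),
                        vmax = seq(60, 140, length.out = 60))
    grid_ss <- mapply(ss_of, grid$km, grid$vmax, MoreArgs = list(d = d))
    expect_lte(fit$residual_ss, min(grid_ss) + 1e-9)
  }
})

test_that("sequence molar mass sums average residue masses plus water", {
  expect_equal(mw_from_sequence("G"), 75.07, tolerance = 1e-4)
  expect_equal(mw_from_sequence("GG"), 132.12, tolerance = 1e-4)
  expect_error(mw_from_sequence(""), "non-empty")
  expect_error(mw_from_sequence("GXZ"), "unknown amino-acid")
  # cross-check against an independent implementation
  seqs <- c("MKTAYIAKQR", "ACDEFGHIKLMNPQRSTVWY", "PPPPGGGG")
  for (sq in seqs)
    expect_equal(mw_from_sequence(sq),
                 seqinr::pmw(strsplit(sq, "")[[1]]),
                 tolerance = 1e-3)
})

test_that("turnover number conversion is dimensionally exact and invertible", {
  expect_equal(kcat_from_vmax(1, 60000), 1.0)
  expect_equal(kcat_from_vmax(0, 27730), 0)
  expect_equal(kcat_from_vmax(100.4, 27730), 46.4, tolerance = 1e-3)
  # round trip vmax -> kcat -> vmax
  for (m in c(27730, 50000, 111000)) {
    kc <- kcat_from_vmax(87.9, m)
    expect_equal(kc * 60000 / m, 87.9, tolerance = 1e-12)
  }
})

test_that("displacement fit honours the half-maximum definition", {
  d <- simulate_displacement(3.51e-3,
                             cfg = sim_config(seed = 11, noise_cv = 0.03))
  fit <- fit_displacement(d, mode = "homologous_dilution")
  mid <- fit$bottom + (fit$top - fit$bottom) /
    (1 + (fit$x50 / fit$x50))
  expect_equal(mid, (fit$top + fit$bottom) / 2, tolerance = 1e-10)
  expect_true(fit$converged)
  expect_gt(fit$top, fit$bottom)
})

test_that("EC50 and IC50 recovery from noisy isotherms stays within 15%", {
  rec <- function(x50_true, mode) {
    vapply(1:40, function(s) {
      d <- simulate_displacement(x50_true,
                                 cfg = sim_config(seed = 100 + s,
                                                  noise_cv = 0.03))
      abs(fit_displacement(d, mode = mode)$x50 - x50_true) / x50_true
    }, 0)
  }
  expect_lt(median(rec(3.51e-3, "homologous_dilution")), 0.15)
  expect_lt(median(rec(0.74e-3, "heterologous_inhibition")), 0.15)
})

test_that("displacement fit is invariant to a common signal scale", {
  d <- simulate_displacement(1e-3, cfg = sim_config(seed = 5, noise_cv = 0.02))
  f1 <- fit_displacement(d)
  d2 <- transform(d, signal = signal * 4.2, background = background * 4.2)
  f2 <- fit_displacement(d2)
  expect_equal(f2$x50, f1$x50, tolerance = 1e-6)
  expect_equal(f2$top, 4.2 * f1$top, tolerance = 1e-6)
})

test_that("a free Hill slope recovers 1 on one-site data and flat data errors", {
  L <- 10^seq(-5, -1, length.out = 11)
  y <- 30 + (900 - 30) / (1 + L / 2e-3)
  fit <- fit_displacement(data.frame(conc_M = L, signal = y),
                          fix_hill = FALSE)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  expect_error(fit_displacement(data.frame(conc_M = L, signal = rep(5, 11))),
               "flat")
})
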