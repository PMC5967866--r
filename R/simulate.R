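#' Simulation configuration
#'
#' Shared settings for all data simulators. A seed is mandatory so every
#' simulated dataset is reproducible; each simulator call seeds its own
#' RNG stream locally and restores the global RNG state afterwards (no
#' hidden global state).
#'
#' @param seed Integer seed (required).
#' @param noise_cv Fractional coefficient of variation of the
#'   multiplicative Gaussian measurement noise (default 0.05, typical for
#'   radiometric assays, which show roughly constant CV).
#' @param n_replicates Replicates per condition (default 3).
#' @param time_grid Sampling times in seconds for time-course simulators
#'   (default the quench-sampling grid 0-120 s used in fast flux assays).
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(seed = 1)
#' @export
sim_config <- function(seed, noise_cv = 0.05, n_replicates = 3,
                       time_grid = c(0, 5, 10, 15, 30, 60, 90, 120)) {
  if (missing(seed)) .stopf("'seed' must be given explicitly")
  .check_num(seed, "seed")
  .check_num(noise_cv, "noise_cv", nonneg = TRUE)
  .check_num(n_replicates, "n_replicates", positive = TRUE)
  .check_num(time_grid, "time_grid", len = NA, nonneg = TRUE)
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 time_grid = sort(unique(time_grid))),
            class = "sim_config")
}

# multiplicative Gaussian noise, CV-parameterized, truncated at zero
.mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  x * pmax(0, 1 + stats::rnorm(length(x), 0, cv))
}

# mM * L -> nmol
.mM_L_to_nmol <- function(c_mM, v_L) c_mM * v_L * 1e6

#' Simulate passive (uncoupled) substrate equilibration
#'
#' Noise-free mean follows the first-order exchange ODE
#' \deqn{dC_{in}/dt = k_{eq}(C_{out} - C_{in}) - k_{leak} C_{in}}
#' integrated numerically; with no leak this is the closed form
#' `C_out * (1 - exp(-k_eq t))`, which saturates at the external
#' concentration — a purely passive mechanism can never exceed
#' fold-accumulation 1. Measured amounts are `C_in * V_internal` times an
#' optional, purely phenomenological vesicle-integrity factor
#' `f(t) = floor + (1 - floor) exp(-integrity_decay * t)` that mimics the
#' peak-then-decline shape seen in real uptake records (declining
#' retention of accumulated label); by default it is off (`f = 1`,
#' monotone uptake). Multiplicative Gaussian noise of CV `noise_cv` is
#' applied per point and replicate.
#'
#' @param c_out External substrate concentration, mM.
#' @param k_eq First-order equilibration rate constant, s^-1.
#' @param leak First-order loss rate constant, s^-1 (default 0).
#' @param v_internal Total intraliposomal volume, L.
#' @param cfg A [sim_config()].
#' @param integrity_decay Rate (s^-1) of the optional integrity decline
#'   (default 0 = off).
#' @param integrity_floor Asymptote of the integrity factor in [0, 1]
#'   (default 0.6).
#' @return An [uptake_time_course()] in nmol with the noise-free mean
#'   curve attached as attribute `truth` (data frame `time_s`, `c_in_mM`,
#'   `amount_nmol`).
#' @examples
#' cfg <- sim_config(seed = 7, noise_cv = 0)
#' tc <- simulate_passive_uptake(0.5, 0.2, v_internal = 7.49e-8, cfg = cfg)
#' @export
simulate_passive_uptake <- function(c_out, k_eq, leak = 0, v_internal, cfg,
                                    integrity_decay = 0,
                                    integrity_floor = 0.6) {
  .check_num(c_out, "c_out", nonneg = TRUE)
  .check_num(k_eq, "k_eq", nonneg = TRUE)
  .check_num(leak, "leak", nonneg = TRUE)
  .check_num(v_internal, "v_internal", positive = TRUE)
  stopifnot(inherits(cfg, "sim_config"))
  .check_num(integrity_decay, "integrity_decay", nonneg = TRUE)
  .check_num(integrity_floor, "integrity_floor", nonneg = TRUE)
  tg <- cfg$time_grid
  rhs <- function(t, y, p)
    list(p$k_eq * (p$c_out - y[1]) - p$leak * y[1])
  sol <- deSolve::ode(y = c(C = 0), times = tg, func = rhs,
                      parms = list(k_eq = k_eq, leak = leak, c_out = c_out),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  c_in <- sol[, "C"]
  integ <- integrity_floor + (1 - integrity_floor) * exp(-integrity_decay * tg)
  if (integrity_decay == 0) integ <- rep(1, length(tg))
  amount <- .mM_L_to_nmol(c_in, v_internal) * integ
  withr::with_seed(cfg$seed, {
    val <- unlist(lapply(seq_len(cfg$n_replicates), function(i)
      .mult_noise(amount, cfg$noise_cv)))
  })
  tc <- uptake_time_course(rep(tg, cfg$n_replicates), val, "nmol",
                           replicate = rep(seq_len(cfg$n_replicates),
                                           each = length(tg)),
                           condition = "simulated passive uptake")
  attr(tc, "truth") <- data.frame(time_s = tg, c_in_mM = c_in,
                                  amount_nmol = amount)
  tc
}

#' Simulate ion-coupled concentrative uptake
#'
#' Mean internal concentration
#' `C_in(t) = fold_limit * c_out * (1 - exp(-k t))`: exponential approach
#' to a steady-state accumulation `fold_limit`-fold above the external
#' concentration, the behaviour of a symporter driven by an ion gradient.
#' `fold_limit = 1` reduces to the passive closed form.
#'
#' @param c_out External substrate concentration, mM.
#' @param fold_limit Steady-state fold accumulation, `>= 1`.
#' @param k Approach rate constant, s^-1.
#' @inheritParams simulate_passive_uptake
#' @return An [uptake_time_course()] in nmol with attribute `truth`.
#' @examples
#' cfg <- sim_config(seed = 3)
#' tc <- simulate_coupled_uptake(0.0025, 150, 0.05,
#'                               v_internal = 7.49e-8, cfg = cfg)
#' @export
simulate_coupled_uptake <- function(c_out, fold_limit, k, v_internal, cfg) {
  .check_num(c_out, "c_out", nonneg = TRUE)
  .check_num(fold_limit, "fold_limit")
  if (fold_limit < 1) .stopf("'fold_limit' must be >= 1")
  .check_num(k, "k", nonneg = TRUE)
  .check_num(v_internal, "v_internal", positive = TRUE)
  stopifnot(inherits(cfg, "sim_config"))
  tg <- cfg$time_grid
  c_in <- fold_limit * c_out * (1 - exp(-k * tg))
  amount <- .mM_L_to_nmol(c_in, v_internal)
  withr::with_seed(cfg$seed, {
    val <- unlist(lapply(seq_len(cfg$n_replicates), function(i)
      .mult_noise(amount, cfg$noise_cv)))
  })
  tc <- uptake_time_course(rep(tg, cfg$n_replicates), val, "nmol",
                           replicate = rep(seq_len(cfg$n_replicates),
                                           each = length(tg)),
                           condition = "simulated coupled uptake")
  attr(tc, "truth") <- data.frame(time_s = tg, c_in_mM = c_in,
                                  amount_nmol = amount)
  tc
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' Rates `v = vmax * S / (km + S)` on a log-spaced substrate grid with
#' multiplicative replicate noise.
#'
#' @param km Michaelis constant, mM.
#' @param vmax Maximal velocity, umol mg^-1 min^-1.
#' @param grid Substrate concentrations, mM (default 8 log-spaced points
#'   spanning 0.5-50 mM).
#' @param cfg A [sim_config()].
#' @return A data frame (`rate_table` schema) with columns `conc_mM`,
#'   `rate`, `replicate`.
#' @examples
#' simulate_mm_rates(8.69, 100.4, cfg = sim_config(seed = 1))
#' @export
simulate_mm_rates <- function(km, vmax,
                              grid = exp(seq(log(0.5), log(50),
                                             length.out = 8)),
                              cfg) {
  .check_num(km, "km", positive = TRUE)
  .check_num(vmax, "vmax", positive = TRUE)
  .check_num(grid, "grid", len = NA, positive = TRUE)
  stopifnot(inherits(cfg, "sim_config"))
  mean_v <- vmax * grid / (km + grid)
  withr::with_seed(cfg$seed, {
    rate <- unlist(lapply(seq_len(cfg$n_replicates), function(i)
      .mult_noise(mean_v, cfg$noise_cv)))
  })
  data.frame(conc_mM = rep(grid, cfg$n_replicates),
             rate = rate,
             replicate = rep(seq_len(cfg$n_replicates), each = length(grid)))
}

#' Simulate a displacement / inhibition isotherm
#'
#' Log-logistic mean
#' `y = bottom + (top - bottom) / (1 + (L / x50)^hill)` plus a constant
#' non-proximity background channel and multiplicative noise; the schema
#' matches what [fit_displacement()] consumes.
#'
#' @param x50 Midpoint concentration, M.
#' @param hill Hill slope (default 1).
#' @param top,bottom Plateau signals (default 1000 and 50 cpm-like units).
#' @param grid Ligand concentrations, M (default 9 log-spaced points
#'   centred two decades around `x50`).
#' @param background Constant non-proximity background added to every
#'   point (default 100).
#' @param cfg A [sim_config()].
#' @return A data frame (`dose_response` schema) with columns `conc_M`,
#'   `signal`, `background`, `replicate`.
#' @examples
#' simulate_displacement(3.51e-3, cfg = sim_config(seed = 2, noise_cv = 0.03))
#' @export
simulate_displacement <- function(x50, hill = 1, top = 1000, bottom = 50,
                                  grid = NULL, background = 100, cfg) {
  .check_num(x50, "x50", positive = TRUE)
  .check_num(hill, "hill", positive = TRUE)
  .check_num(top, "top"); .check_num(bottom, "bottom")
  if (top <= bottom) .stopf("'top' must exceed 'bottom'")
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(grid))
    grid <- 10^seq(log10(x50) - 2, log10(x50) + 2, length.out = 9)
  mean_y <- bottom + (top - bottom) / (1 + (grid / x50)^hill) + background
  withr::with_seed(cfg$seed, {
    sig <- unlist(lapply(seq_len(cfg$n_replicates), function(i)
      .mult_noise(mean_y, cfg$noise_cv)))
  })
  data.frame(conc_M = rep(grid, cfg$n_replicates),
             signal = sig,
             background = background,
             replicate = rep(seq_len(cfg$n_replicates), each = length(grid)))
}

#' Simulate single-channel current-voltage data
#'
#' Produces the unitary (open-level) current-voltage table
#' `i = g * (V - v_rev)` with multiplicative measurement noise, and
#' optionally raw gated current traces from `n_channels` independent
#' two-state (closed/open) Markov channels with stationary open
#' probability `open_prob`. With several channels the noise-free trace
#' occupies `n_channels + 1` discrete current levels, as superimposed
#' unitary conductances do in planar-bilayer recordings.
#'
#' @param g Single-channel conductance, pS.
#' @param v_rev Reversal potential, mV (default 0, symmetric solutions).
#' @param open_prob Stationary open probability in (0, 1) (default 0.5).
#' @param n_channels Number of reconstituted channels (default 1).
#' @param voltages Holding potentials, mV (default -100..100 in 25 mV
#'   steps, excluding `v_rev` only if all currents would vanish).
#' @param cfg A [sim_config()].
#' @param return_trace If `TRUE`, attach per-voltage gated traces
#'   (`trace_n` points each, transition probability `gating_p` per step)
#'   as attribute `traces`.
#' @param trace_n Points per gated trace (default 2000).
#' @param gating_p Per-step probability scale of the two-state gating
#'   (default 0.05).
#' @return A data frame (`iv_table` schema) with columns `voltage_mV`,
#'   `current_pA`; optional attribute `traces`.
#' @examples
#' simulate_iv(92, cfg = sim_config(seed = 5, noise_cv = 0.02))
#' @export
simulate_iv <- function(g, v_rev = 0, open_prob = 0.5, n_channels = 1,
                        voltages = seq(-100, 100, by = 25), cfg,
                        return_trace = FALSE, trace_n = 2000,
                        gating_p = 0.05) {
  .check_num(g, "g", nonneg = TRUE)
  .check_num(v_rev, "v_rev")
  .check_num(open_prob, "open_prob")
  if (open_prob <= 0 || open_prob >= 1)
    .stopf("'open_prob' must lie strictly in (0, 1)")
  .check_num(n_channels, "n_channels", positive = TRUE)
  .check_num(voltages, "voltages", len = NA)
  stopifnot(inherits(cfg, "sim_config"))
  unit_i <- g * 1e-3 * (voltages - v_rev)   # pS * mV = 1e-3 pA
  withr::with_seed(cfg$seed, {
    current <- .mult_noise(unit_i, cfg$noise_cv)
    traces <- NULL
    if (return_trace) {
      p_co <- gating_p * open_prob          # closed -> open
      p_oc <- gating_p * (1 - open_prob)    # open -> closed
      traces <- lapply(seq_along(voltages), function(j) {
        states <- matrix(0L, nrow = trace_n, ncol = n_channels)
        states[1, ] <- stats::rbinom(n_channels, 1, open_prob)
        for (t in 2:trace_n) {
          u <- stats::runif(n_channels)
          open <- states[t - 1, ] == 1L
          states[t, ] <- ifelse(open, ifelse(u < p_oc, 0L, 1L),
                                ifelse(u < p_co, 1L, 0L))
        }
        rowSums(states) * g * 1e-3 * (voltages[j] - v_rev)
      })
      names(traces) <- paste0(voltages, "mV")
    }
  })
  out <- data.frame(voltage_mV = voltages, current_pA = current)
  if (return_trace) attr(out, "traces") <- traces
  out
}
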