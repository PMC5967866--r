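# Average residue masses (g/mol), ExPASy convention; free water added once
# per chain when summing a sequence.
.RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MASS <- 18.01528

#' Initial uptake rate from a time course
#'
#' Extracts the initial transport rate as the least-squares slope of
#' amount versus time over the window `[0, window]`, normalized per mg of
#' reconstituted protein per minute. If a measured `t = 0` point is
#' present the fitted line is forced through it; otherwise an ordinary
#' intercept is estimated. Time courses in cpm are converted to moles via
#' [counts_to_moles()] first.
#'
#' @param tc An [uptake_time_course()].
#' @param assay An [assay_spec()]; `protein_mass` (ug) is required, and
#'   the radiochemistry fields as well when `tc` is in cpm.
#' @param window Width of the initial-rate window in seconds (default 5 s,
#'   the conventional quenched-sampling window for fast flux).
#' @return Initial rate in umol substrate per mg protein per minute.
#' @examples
#' tc <- uptake_time_course(c(0, 1, 2, 3, 4, 5), 0.02 * c(0, 1, 2, 3, 4, 5))
#' a  <- assay_spec(0.02, 100, 5, protein_mass = 1)
#' initial_rate(tc, a)   # slope 0.02 nmol/s over 1 ug -> 1.2 umol/mg/min
#' @export
initial_rate <- function(tc, assay, window = 5) {
  stopifnot(inherits(tc, "uptake_time_course"), inherits(assay, "assay_spec"))
  .check_num(window, "window", positive = TRUE)
  if (is.null(assay$protein_mass))
    .stopf("'protein_mass' must be present in the assay spec")
  v <- tc$value
  if (attr(tc, "value_type") == "cpm")
    v <- counts_to_moles(v, assay) * 1e9   # mol -> nmol
  agg <- stats::aggregate(list(value = v), list(time_s = tc$time_s), mean)
  agg <- agg[agg$time_s <= window, , drop = FALSE]
  if (nrow(agg) < 2)
    .stopf("need at least 2 averaged points within [0, %g] s", window)
  if (any(agg$time_s == 0)) {
    v0 <- agg$value[agg$time_s == 0]
    slope <- sum((agg$value - v0) * agg$time_s) / sum(agg$time_s^2)
  } else {
    slope <- stats::coef(stats::lm(value ~ time_s, data = agg))[["time_s"]]
  }
  # nmol/s -> umol/min, per mg protein (protein_mass in ug)
  slope * 60 / assay$protein_mass
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Unweighted nonlinear least squares of
#' \deqn{v = V_{max} S / (K_m + S)}
#' performed in log-parameter space (log Km, log Vmax) so both parameters
#' stay positive along the optimization path. Initialization: Km at the
#' median substrate concentration and Vmax at 1.2 times the largest
#' observed rate. Standard errors on the natural scale are obtained by the
#' delta method from the asymptotic covariance of the log parameters.
#'
#' @param data A data frame with columns `conc_mM` (substrate, mM, > 0)
#'   and `rate` (umol mg^-1 min^-1, >= 0); replicate rows per
#'   concentration are allowed. An optional `weights` choice of "none"
#'   (default, the usual Prism-style unweighted fit) or "1/v2"
#'   (relative weighting) is available.
#' @param protomer_mass Optional protomer molar mass (g/mol); when given,
#'   the turnover number kcat is derived via [kcat_from_vmax()].
#' @param weights Weighting scheme, see above.
#' @return An object of class `mm_fit`: `km` (mM), `vmax`
#'   (umol mg^-1 min^-1), `km_se`, `vmax_se`, optional `kcat` (s^-1),
#'   `converged`, `residual_ss`, and the underlying `fit` object.
#' @examples
#' s <- c(0.5, 1, 2, 5, 10, 20, 50)
#' fit_michaelis_menten(data.frame(conc_mM = s,
#'                                 rate = 100.4 * s / (8.69 + s)))
#' @export
fit_michaelis_menten <- function(data, protomer_mass = NULL,
                                 weights = c("none", "1/v2")) {
  weights <- match.arg(weights)
  data <- .require_cols(data, c("conc_mM", "rate"), "rate table")
  if (any(data$conc_mM <= 0)) .stopf("substrate concentrations must be > 0")
  if (any(data$rate < 0)) .stopf("rates must be >= 0")
  if (length(unique(data$conc_mM)) < 4)
    .stopf("need rates at >= 4 distinct substrate concentrations")
  w <- if (weights == "1/v2") 1 / pmax(data$rate, .Machine$double.eps)^2
       else rep(1, nrow(data))
  start <- list(lkm = log(stats::median(data$conc_mM)),
                lvmax = log(1.2 * max(data$rate)))
  fit <- try(minpack.lm::nlsLM(
    rate ~ exp(lvmax) * conc_mM / (exp(lkm) + conc_mM),
    data = data, start = start, weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-12, ptol = 1e-12)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    .stopf("Michaelis-Menten fit failed to converge: %s",
           attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  km <- exp(cf[["lkm"]]); vmax <- exp(cf[["lvmax"]])
  out <- list(km = km, vmax = vmax,
              km_se = km * se[["lkm"]], vmax_se = vmax * se[["lvmax"]],
              kcat = if (!is.null(protomer_mass))
                kcat_from_vmax(vmax, protomer_mass) else NULL,
              converged = fit$convInfo$isConv,
              residual_ss = sum(stats::residuals(fit)^2),
              fit = fit)
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km = %.4g +/- %.2g mM, Vmax = %.4g +/- %.2g umol/mg/min\n",
              x$km, x$km_se, x$vmax, x$vmax_se))
  if (!is.null(x$kcat)) cat(sprintf("  kcat = %.4g s^-1\n", x$kcat))
  cat(sprintf("  converged: %s, residual SS = %.4g\n",
              x$converged, x$residual_ss))
  invisible(x)
}

#' Average molar mass of a protein from its sequence
#'
#' Sums the average residue masses of the standard twenty amino acids and
#' adds one water for the free termini.
#'
#' @param seq Amino-acid sequence, one-letter codes (case-insensitive).
#' @return Molar mass in g/mol.
#' @examples
#' mw_from_sequence("G")    # 75.07, free glycine
#' @export
mw_from_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || nchar(seq) == 0)
    .stopf("'seq' must be a single non-empty amino-acid string")
  aa <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(aa), names(.RESIDUE_MASS))
  if (length(bad))
    .stopf("unknown amino-acid code(s): %s", paste(bad, collapse = ", "))
  sum(.RESIDUE_MASS[aa]) + .WATER_MASS
}

#' Turnover number from specific maximal velocity
#'
#' Converts a maximal transport velocity expressed per milligram of
#' protein into a per-molecule turnover number:
#' \deqn{k_{cat} = V_{max} \times M / 60000}
#' where Vmax is in umol mg^-1 min^-1 and M is the protomer molar mass in
#' g/mol; the factor 60,000 collapses the minute-to-second and
#' umol/mg-to-mol/g conversions.
#'
#' @param vmax Maximal velocity, umol mg^-1 min^-1, `>= 0`.
#' @param protomer_mass Protomer molar mass, g/mol, `> 0`.
#' @return Turnover number in s^-1.
#' @examples
#' kcat_from_vmax(1, 60000)      # 1 s^-1 (unit identity)
#' kcat_from_vmax(100.4, 27730)  # ~46.4 s^-1
#' @export
kcat_from_vmax <- function(vmax, protomer_mass) {
  .check_num(vmax, "vmax", nonneg = TRUE, len = NA)
  .check_num(protomer_mass, "protomer_mass", positive = TRUE)
  vmax * protomer_mass / 60000
}

#' Fit a displacement or inhibition isotherm
#'
#' Four-parameter log-logistic fit of a dose-response curve,
#' \deqn{y = bottom + \frac{top - bottom}{1 + ([L]/X_{50})^{h}}}
#' after subtraction of the non-proximity background. `X50` is reported as
#' an EC50 in homologous-dilution mode (cold ligand diluting a fixed hot
#' ligand) or an IC50 in heterologous-inhibition mode. `X50` is optimized
#' in log space; the Hill slope can be fixed to 1 (the expectation for
#' simple one-site displacement).
#'
#' @param data A data frame with columns `conc_M` (ligand concentration,
#'   M, >= 0) and `signal` (counts or normalized), plus either a
#'   `background` column or the `background` argument.
#' @param mode "homologous_dilution" or "heterologous_inhibition";
#'   controls only how X50 is labelled.
#' @param background Scalar non-proximity background subtracted from every
#'   point (ignored when the data carry a `background` column).
#' @param fix_hill If `TRUE` (default) the Hill slope is fixed at 1;
#'   otherwise it is a free parameter.
#' @return An object of class `displacement_fit`: `x50` (M), `x50_se`,
#'   `hill`, `top`, `bottom`, their standard errors, `mode`, `converged`,
#'   `residual_ss` and the underlying `fit`.
#' @examples
#' L <- 10^seq(-5, -1, length.out = 9)
#' y <- 20 + (1000 - 20) / (1 + L / 3.51e-3)
#' fit_displacement(data.frame(conc_M = L, signal = y + 5), background = 5)
#' @export
fit_displacement <- function(data,
                             mode = c("homologous_dilution",
                                      "heterologous_inhibition"),
                             background = 0, fix_hill = TRUE) {
  mode <- match.arg(mode)
  data <- .require_cols(data, c("conc_M", "signal"), "dose-response table")
  if (any(data$conc_M < 0)) .stopf("ligand concentrations must be >= 0")
  if (length(unique(data$conc_M)) < 5)
    .stopf("need >= 5 distinct ligand concentrations")
  bg <- if ("background" %in% names(data)) data$background else background
  y <- data$signal - bg
  rng <- diff(range(y))
  if (rng <= 1e-9 * max(abs(y), 1))
    .stopf("signal is flat after background subtraction; nothing to fit")
  df <- data.frame(L = data$conc_M, y = y)
  lx0 <- log(exp(mean(log(df$L[df$L > 0]))))
  start <- list(top = max(y), bottom = min(y), lx50 = lx0)
  form <- if (fix_hill)
    y ~ bottom + (top - bottom) / (1 + (L / exp(lx50)))
  else
    y ~ bottom + (top - bottom) / (1 + (L / exp(lx50))^hill)
  if (!fix_hill) start$hill <- 1
  fit <- try(minpack.lm::nlsLM(form, data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-12, ptol = 1e-12)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    .stopf("displacement fit failed to converge: %s",
           attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  x50 <- exp(cf[["lx50"]])
  out <- list(x50 = x50, x50_se = x50 * se[["lx50"]],
              hill = if (fix_hill) 1 else cf[["hill"]],
              hill_se = if (fix_hill) NA_real_ else se[["hill"]],
              top = cf[["top"]], top_se = se[["top"]],
              bottom = cf[["bottom"]], bottom_se = se[["bottom"]],
              mode = mode,
              converged = fit$convInfo$isConv,
              residual_ss = sum(stats::residuals(fit)^2),
              fit = fit)
  class(out) <- "displacement_fit"
  out
}

#' @export
print.displacement_fit <- function(x, ...) {
  lab <- if (x$mode == "homologous_dilution") "EC50" else "IC50"
  cat(sprintf("Displacement fit (%s): %s = %.4g +/- %.2g M\n",
              x$mode, lab, x$x50, x$x50_se))
  cat(sprintf("  top = %.4g, bottom = %.4g, hill = %.3g\n",
              x$top, x$bottom, x$hill))
  cat(sprintf("  converged: %s, residual SS = %.4g\n",
              x$converged, x$residual_ss))
  invisible(x)
}
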