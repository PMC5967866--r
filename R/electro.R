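#' Nernst diffusion potential
#'
#' Equilibrium transmembrane potential for a single permeant ion species,
#' \deqn{E = \frac{RT}{zF}\ln\frac{[X]_{out}}{[X]_{in}}}
#' computed on concentrations (activity coefficients are ignored, as is
#' conventional for ionophore-clamped vesicle experiments). With the K+
#' ionophore valinomycin this is the potential imposed by a K+ gradient:
#' a 1:100 in:out K+ distribution at 298.15 K gives +118 mV
#' (inside-positive).
#'
#' @param k_in Internal ion concentration, mM, `> 0`.
#' @param k_out External ion concentration, mM, `> 0`.
#' @param temperature Absolute temperature, K (default 298.15 K).
#' @param z Ion charge number (integer, non-zero; +1 for K+).
#' @return Membrane potential in mV; positive means inside-positive when
#'   `k_out > k_in` for a cation.
#' @examples
#' nernst_potential(k_in = 1, k_out = 100)   # +118 mV
#' nernst_potential(k_in = 10, k_out = 10)   # 0 mV
#' @export
nernst_potential <- function(k_in, k_out, temperature = .CONST$T_default,
                             z = 1) {
  .check_num(k_in, "k_in", positive = TRUE)
  .check_num(k_out, "k_out", positive = TRUE)
  .check_num(temperature, "temperature", positive = TRUE)
  .check_num(z, "z")
  if (z == 0) .stopf("'z' must be a non-zero integer charge")
  1000 * (.CONST$R * temperature) / (z * .CONST$F) * log(k_out / k_in)
}

#' Single-channel conductance from a current-voltage relation
#'
#' Ordinary least-squares fit of the ohmic line
#' `current = g * (V - V_rev)` to unitary current-voltage data. The slope
#' in pA/mV equals the conductance in nS and is reported in pS; the
#' reversal potential is the voltage-axis intercept. Extrapolation of the
#' reversal potential beyond the measured voltage range is flagged.
#'
#' @param data A data frame with columns `voltage_mV` and `current_pA`,
#'   at least 3 points with distinct voltages.
#' @return An object of class `channel_fit`: `conductance` (pS),
#'   `conductance_se` (pS), `reversal_potential` (mV),
#'   `reversal_extrapolated` flag, `r_squared`, and the underlying `fit`.
#' @examples
#' v <- seq(-100, 100, by = 25)
#' conductance_from_iv(data.frame(voltage_mV = v, current_pA = 0.092 * v))
#' @export
conductance_from_iv <- function(data) {
  data <- .require_cols(data, c("voltage_mV", "current_pA"), "I-V table")
  if (nrow(data) < 3) .stopf("need at least 3 I-V points")
  if (length(unique(data$voltage_mV)) < 2)
    .stopf("singular design: all voltages identical")
  fit <- stats::lm(current_pA ~ voltage_mV, data = data)
  cf <- stats::coef(fit)
  slope <- cf[["voltage_mV"]]           # pA/mV == nS
  v_rev <- -cf[["(Intercept)"]] / slope
  rng <- range(data$voltage_mV)
  # summary.lm warns on exact (zero-residual) lines; harmless here
  smry <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(
    conductance = 1000 * slope,
    conductance_se = 1000 * smry$coefficients["voltage_mV", 2],
    reversal_potential = v_rev,
    reversal_extrapolated = (v_rev < rng[1] || v_rev > rng[2]),
    r_squared = smry$r.squared,
    fit = fit), class = "channel_fit")
}

#' @export
print.channel_fit <- function(x, ...) {
  cat(sprintf("Ohmic channel fit: g = %.4g +/- %.2g pS, V_rev = %.3g mV%s (R^2 = %.4f)\n",
              x$conductance, x$conductance_se, x$reversal_potential,
              if (x$reversal_extrapolated) " [extrapolated]" else "",
              x$r_squared))
  invisible(x)
}
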