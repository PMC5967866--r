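#' Uptake time course
#'
#' Container for one radiotracer uptake time course. Amounts may be given
#' either as chemical amount per assay (nmol) or as raw scintillation
#' counts (cpm); the `value_type` flag records which, so downstream code
#' knows whether a radiochemical conversion is still required. Replicates
#' share the same nominal time points and are identified by `replicate`.
#' Uptake need not be monotone: a peak followed by a decline is an
#' expected shape for passive flux assays.
#'
#' @param time_s Time in seconds, non-negative; strictly increasing within
#'   each replicate.
#' @param value Measured amounts, `>= 0`, same length as `time_s`.
#' @param value_type Either "nmol" or "cpm".
#' @param replicate Optional replicate labels (recycled if length 1).
#' @param condition Optional free-text metadata (buffer, membrane
#'   potential, inhibitor).
#' @return An object of class `uptake_time_course`: a data frame with
#'   columns `time_s`, `value`, `replicate` and attributes `value_type`,
#'   `condition`.
#' @examples
#' uptake_time_course(c(0, 5, 15, 60, 120),
#'                    c(0, 0.08, 0.19, 0.13, 0.11))
#' @export
uptake_time_course <- function(time_s, value, value_type = c("nmol", "cpm"),
                               replicate = NULL, condition = NULL) {
  value_type <- match.arg(value_type)
  .check_num(time_s, "time_s", len = NA)
  .check_num(value, "value", len = NA, nonneg = TRUE)
  if (length(time_s) != length(value))
    .stopf("'time_s' and 'value' must have equal length")
  if (any(time_s < 0)) .stopf("'time_s' must be >= 0")
  if (is.null(replicate)) replicate <- 1L
  replicate <- rep_len(replicate, length(time_s))
  for (r in unique(replicate)) {
    tt <- time_s[replicate == r]
    if (any(diff(tt) <= 0))
      .stopf("times must be strictly increasing within replicate '%s'", r)
  }
  df <- data.frame(time_s = time_s, value = value, replicate = replicate,
                   stringsAsFactors = FALSE)
  structure(df, value_type = value_type, condition = condition,
            class = c("uptake_time_course", "data.frame"))
}

#' Convert scintillation counts to moles of substrate
#'
#' Raw counts per minute are corrected for counting efficiency, converted
#' to disintegrations per minute, expressed in millicuries
#' (2.22e9 dpm/mCi) and divided by the specific radioactivity
#' (mCi/mmol) to give millimoles, then moles.
#'
#' @param counts Counts per minute (cpm), `>= 0`; vectorized.
#' @param assay An [assay_spec()] carrying `specific_activity` (mCi/mmol)
#'   and `counting_efficiency`.
#' @return Amount of substrate in mol.
#' @examples
#' a <- assay_spec(0.02, 100, 0.5, specific_activity = 50,
#'                 counting_efficiency = 1)
#' counts_to_moles(2.22e9, a)   # one mCi worth of counts -> 2e-5 mol
#' @export
counts_to_moles <- function(counts, assay) {
  stopifnot(inherits(assay, "assay_spec"))
  .check_num(counts, "counts", len = NA, nonneg = TRUE)
  if (is.null(assay$specific_activity) || is.null(assay$counting_efficiency))
    .stopf(paste("radiochemistry conversion requires 'specific_activity'",
                 "and 'counting_efficiency' in the assay spec"))
  dpm <- counts / assay$counting_efficiency
  mCi <- dpm / .CONST$dpm_per_mCi
  .mmol_to_mol(mCi / assay$specific_activity)
}

#' Internal substrate concentration
#'
#' Divides the accumulated amount of substrate by the total
#' intraliposomal volume, reporting millimolar.
#'
#' @param amount Accumulated substrate, mol; vectorized.
#' @param v_internal Total intraliposomal volume, L (see
#'   [internal_volume()]).
#' @return Internal concentration in mM.
#' @examples
#' internal_concentration(0.1869e-9, 7.49e-8)  # ~2.49 mM
#' @export
internal_concentration <- function(amount, v_internal) {
  .check_num(amount, "amount", len = NA, nonneg = TRUE)
  .check_num(v_internal, "v_internal", positive = TRUE)
  .M_to_mM(amount / v_internal)
}

#' Fold accumulation of substrate
#'
#' Ratio of internal to external substrate concentration. For passive
#' (uncoupled) flux of a solute with no driving potential the equilibrium
#' expectation is 1; ion-coupled concentrative transport can exceed it by
#' orders of magnitude.
#'
#' @param c_in Internal concentration (any unit); vectorized.
#' @param c_out External concentration, same unit, `> 0`.
#' @return Dimensionless fold accumulation `c_in / c_out`.
#' @examples
#' fold_accumulation(2.49, 0.5)   # ~5-fold at the uptake peak
#' @export
fold_accumulation <- function(c_in, c_out) {
  .check_num(c_in, "c_in", len = NA, nonneg = TRUE)
  .check_num(c_out, "c_out", len = NA)
  if (any(c_out <= 0)) .stopf("'c_out' must be > 0")
  c_in / c_out
}

#' Peak and plateau of an uptake time course
#'
#' Replicates are averaged per time point first; the peak is the maximum
#' averaged amount and the plateau the mean of the last `plateau_n`
#' averaged points. The standard error of the mean across replicates is
#' propagated for both.
#'
#' @param tc An [uptake_time_course()].
#' @param plateau_n Number of trailing time points averaged for the
#'   plateau (default 2; set to 1 to use the final point alone).
#' @return A list with `peak` (amount), `peak_time` (s), `plateau`
#'   (amount), `peak_sem` and `plateau_sem` (NA when replicates are
#'   absent), and `mean_course` (the per-time-point averaged data frame).
#' @examples
#' tc <- uptake_time_course(c(0, 5, 15, 60, 120),
#'                          c(0, 1, 3, 2.5, 2.4))
#' summarize_time_course(tc, plateau_n = 2)
#' @export
summarize_time_course <- function(tc, plateau_n = 2) {
  stopifnot(inherits(tc, "uptake_time_course"))
  .check_num(plateau_n, "plateau_n", positive = TRUE)
  agg <- stats::aggregate(value ~ time_s, data = tc, FUN = mean)
  nrep <- stats::aggregate(value ~ time_s, data = tc, FUN = length)$value
  sdv <- stats::aggregate(value ~ time_s, data = tc,
                          FUN = stats::sd)$value
  agg$sem <- ifelse(nrep > 1, sdv / sqrt(nrep), NA_real_)
  agg <- agg[order(agg$time_s), ]
  if (nrow(agg) < plateau_n + 1)
    .stopf("need at least plateau_n + 1 = %d distinct time points, got %d",
           plateau_n + 1, nrow(agg))
  ipk <- which.max(agg$value)
  tail_idx <- seq(nrow(agg) - plateau_n + 1, nrow(agg))
  plateau_sem <- if (all(is.na(agg$sem[tail_idx]))) NA_real_ else
    sqrt(sum(agg$sem[tail_idx]^2, na.rm = TRUE)) / plateau_n
  list(peak = agg$value[ipk],
       peak_time = agg$time_s[ipk],
       plateau = mean(agg$value[tail_idx]),
       peak_sem = agg$sem[ipk],
       plateau_sem = plateau_sem,
       mean_course = agg)
}

#' Classify a transport phenotype from fold-accumulation values
#'
#' A solute that only equilibrates across the membrane (channel,
#' uniporter, facilitated diffusion) cannot accumulate much beyond the
#' external concentration, so its steady-state fold accumulation stays
#' near the passive baseline of 1. Ion-coupled (symport) transport can
#' concentrate substrate far above it. The call is made on the plateau
#' fold: `channel-like` at or below `channel_threshold`, `concentrative`
#' at or above `coupled_threshold`, `indeterminate` in between.
#'
#' @param fold_peak Fold accumulation at the uptake peak.
#' @param fold_plateau Fold accumulation at the plateau.
#' @param c_in_peak,c_in_plateau Internal concentrations (mM) behind the
#'   folds, carried into the report.
#' @param channel_threshold Upper fold bound for a channel-like call
#'   (default 10).
#' @param coupled_threshold Lower fold bound for a concentrative call
#'   (default 50). Must exceed `channel_threshold`.
#' @param coupled_baseline Optional user-supplied thermodynamic limit for
#'   coupled transport (e.g. the fold allowed by the driving-ion
#'   gradient), reported alongside the call.
#' @return An object of class `phenotype_report` with the folds, the
#'   concentrations, the passive baseline (1), both thresholds and the
#'   `call` (one of "channel-like", "concentrative", "indeterminate").
#' @examples
#' classify_phenotype(fold_peak = 4.98, fold_plateau = 3.06)
#' classify_phenotype(fold_peak = 150, fold_plateau = 149.5)
#' @export
classify_phenotype <- function(fold_peak, fold_plateau,
                               c_in_peak = NA_real_, c_in_plateau = NA_real_,
                               channel_threshold = 10, coupled_threshold = 50,
                               coupled_baseline = NULL) {
  .check_num(fold_peak, "fold_peak", nonneg = TRUE)
  .check_num(fold_plateau, "fold_plateau", nonneg = TRUE)
  .check_num(channel_threshold, "channel_threshold", positive = TRUE)
  .check_num(coupled_threshold, "coupled_threshold", positive = TRUE)
  if (channel_threshold >= coupled_threshold)
    .stopf("'channel_threshold' (%g) must be below 'coupled_threshold' (%g)",
           channel_threshold, coupled_threshold)
  call <- if (fold_plateau <= channel_threshold) "channel-like"
          else if (fold_plateau >= coupled_threshold) "concentrative"
          else "indeterminate"
  structure(list(c_in_peak = c_in_peak, c_in_plateau = c_in_plateau,
                 fold_peak = fold_peak, fold_plateau = fold_plateau,
                 passive_baseline = 1.0,
                 coupled_baseline = coupled_baseline,
                 channel_threshold = channel_threshold,
                 coupled_threshold = coupled_threshold,
                 call = call),
            class = "phenotype_report")
}

#' Display-round a fold-accumulation value
#'
#' Folds are reported at full precision in all computations; this helper
#' applies the conventional display rounding only (nearest integer below
#' 10, nearest ten at or above 10), e.g. 4.98 prints as "~5" and 149.5 as
#' "~150".
#'
#' @param fold Fold accumulation value(s).
#' @return Character vector like "~5".
#' @examples
#' format_fold(c(4.98, 3.06, 149.5))
#' @export
format_fold <- function(fold) {
  .check_num(fold, "fold", len = NA, nonneg = TRUE)
  ifelse(fold < 10, paste0("~", round(fold)), paste0("~", 10 * round(fold / 10)))
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("Transport phenotype report\n")
  if (!is.na(x$c_in_peak))
    cat(sprintf("  internal conc (peak)    : %.4g mM\n", x$c_in_peak))
  if (!is.na(x$c_in_plateau))
    cat(sprintf("  internal conc (plateau) : %.4g mM\n", x$c_in_plateau))
  cat(sprintf("  fold at peak            : %.4g (%s)\n",
              x$fold_peak, format_fold(x$fold_peak)))
  cat(sprintf("  fold at plateau         : %.4g (%s)\n",
              x$fold_plateau, format_fold(x$fold_plateau)))
  cat(sprintf("  passive baseline        : %g\n", x$passive_baseline))
  if (!is.null(x$coupled_baseline))
    cat(sprintf("  coupled baseline        : %g\n", x$coupled_baseline))
  cat(sprintf("  thresholds              : channel <= %g, concentrative >= %g\n",
              x$channel_threshold, x$coupled_threshold))
  cat("  call                    :", x$call, "\n")
  invisible(x)
}
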