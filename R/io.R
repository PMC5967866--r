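# column validation shared by every tabular reader and fitter
.require_cols <- function(data, cols, what) {
  if (!is.data.frame(data)) .stopf("%s must be a data frame", what)
  if (nrow(data) == 0) .stopf("%s is empty", what)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  for (cl in cols) {
    if (!is.numeric(data[[cl]]) || anyNA(data[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[cl]]))))
      .stopf("%s column '%s' has non-numeric or missing values (rows %s)",
             what, cl, paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  data
}

.TABLE_SCHEMAS <- list(
  timecourse    = c("time_s", "value"),
  rates         = c("conc_mM", "rate"),
  dose_response = c("conc_M", "signal_cpm"),
  iv            = c("voltage_mV", "current_pA"))

#' Read and validate a measurement table
#'
#' Reads a UTF-8, comma-separated file with a header row and validates it
#' against one of the package's table schemas, with informative errors
#' naming any missing column or non-numeric rows.
#'
#' Schemas (required columns):
#' \describe{
#'   \item{timecourse}{`time_s, value` plus optional `value_type`
#'     ("nmol", the default, or "cpm"), `replicate`, `condition`;
#'     returns an [uptake_time_course()].}
#'   \item{rates}{`conc_mM, rate` plus optional `replicate`; returns a
#'     data frame for [fit_michaelis_menten()].}
#'   \item{dose_response}{`conc_M, signal_cpm` plus optional
#'     `background_cpm`; returns a data frame with columns `conc_M`,
#'     `signal`, `background` for [fit_displacement()].}
#'   \item{iv}{`voltage_mV, current_pA`; returns a data frame for
#'     [conductance_from_iv()].}
#' }
#'
#' @param path Path to a CSV file.
#' @param schema One of "timecourse", "rates", "dose_response", "iv".
#' @return A typed table as described above.
#' @export
load_table <- function(path, schema = c("timecourse", "rates",
                                        "dose_response", "iv")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) .stopf("'%s' contains no data rows", path)
  df <- .require_cols(df, .TABLE_SCHEMAS[[schema]],
                      sprintf("%s table '%s'", schema, basename(path)))
  switch(schema,
    timecourse = {
      vt <- if ("value_type" %in% names(df)) unique(df$value_type) else "nmol"
      if (length(vt) != 1 || !vt %in% c("nmol", "cpm"))
        .stopf("'value_type' must be a single value, 'nmol' or 'cpm'")
      uptake_time_course(df$time_s, df$value, vt,
                         replicate = if ("replicate" %in% names(df))
                           df$replicate else NULL,
                         condition = if ("condition" %in% names(df))
                           paste(unique(df$condition), collapse = "; ")
                         else NULL)
    },
    rates = df[, intersect(c("conc_mM", "rate", "replicate"), names(df))],
    dose_response = data.frame(
      conc_M = df$conc_M, signal = df$signal_cpm,
      background = if ("background_cpm" %in% names(df))
        df$background_cpm else 0),
    iv = df[, c("voltage_mV", "current_pA")])
}

.CONFIG_KEYS <- list(
  liposome = c("r_outer", "m_membrane", "a_headgroup", "lipid_mw"),
  assay = c("lipid_mass", "assay_volume", "external_conc",
            "specific_activity", "counting_efficiency", "protein_mass"),
  thresholds = c("channel", "coupled"),
  options = c("plateau_n"))

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with sections `liposome`, `assay` and (optionally)
#' `thresholds` and `options`, validates every field, and rejects unknown
#' keys with a field-level message. Field names mirror the arguments of
#' [liposome_spec()] and [assay_spec()]; `thresholds` holds `channel` and
#' `coupled` fold cutoffs, `options$plateau_n` the plateau window.
#'
#' @param path Path to a YAML config file.
#' @return A list of class `pipeline_config` with elements `liposome`
#'   (a `liposome_spec`), `assay` (an `assay_spec`), `thresholds` and
#'   `plateau_n`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  unknown_top <- setdiff(names(raw), names(.CONFIG_KEYS))
  if (length(unknown_top))
    .stopf("unknown config section(s): %s", paste(unknown_top, collapse = ", "))
  for (sec in intersect(names(raw), names(.CONFIG_KEYS))) {
    bad <- setdiff(names(raw[[sec]]), .CONFIG_KEYS[[sec]])
    if (length(bad))
      .stopf("unknown key(s) in config section '%s': %s", sec,
             paste(bad, collapse = ", "))
  }
  if (is.null(raw$liposome) || is.null(raw$assay))
    .stopf("config must contain 'liposome' and 'assay' sections")
  lip <- do.call(liposome_spec, raw$liposome)
  asy <- do.call(assay_spec, raw$assay)
  thr <- list(channel = raw$thresholds$channel %||% 10,
              coupled = raw$thresholds$coupled %||% 50)
  structure(list(liposome = lip, assay = asy, thresholds = thr,
                 plateau_n = raw$options$plateau_n %||% 2),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a pipeline configuration in code
#'
#' Programmatic equivalent of [load_config()].
#'
#' @param liposome A [liposome_spec()].
#' @param assay An [assay_spec()].
#' @param channel_threshold,coupled_threshold Phenotype fold cutoffs.
#' @param plateau_n Trailing points averaged for the plateau.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(liposome, assay, channel_threshold = 10,
                            coupled_threshold = 50, plateau_n = 2) {
  stopifnot(inherits(liposome, "liposome_spec"), inherits(assay, "assay_spec"))
  structure(list(liposome = liposome, assay = assay,
                 thresholds = list(channel = channel_threshold,
                                   coupled = coupled_threshold),
                 plateau_n = plateau_n),
            class = "pipeline_config")
}

.q <- function(value, unit) list(value = value, unit = unit)

#' Run the full uptake-to-phenotype pipeline
#'
#' Executes the analysis chain end to end: vesicle geometry (lipids per
#' vesicle, vesicle count, intraliposomal volume), conversion of the
#' measured time course to internal concentrations, fold-accumulation
#' statistics, and the channel-like versus concentrative phenotype call.
#' The report retains every intermediate so the chain can be audited line
#' by line; all quantities carry explicit unit strings.
#'
#' @param config A `pipeline_config` (see [pipeline_config()] /
#'   [load_config()]).
#' @param timecourse An [uptake_time_course()], or a path to a timecourse
#'   CSV (read via [load_table()]).
#' @return A list of class `flux_report` with elements `report_version`,
#'   `geometry`, `uptake`, and `phenotype` (a [classify_phenotype()]
#'   report).
#' @examples
#' cfg <- pipeline_config(liposome_spec(),
#'                        assay_spec(0.02, 100, 0.5))
#' tc <- uptake_time_course(c(0, 5, 15, 60, 120),
#'                          c(0, 0.09, 0.1869, 0.13, 0.1145))
#' run_pipeline(cfg, tc)
#' @export
run_pipeline <- function(config, timecourse) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(timecourse))
    timecourse <- load_table(timecourse, "timecourse")
  stopifnot(inherits(timecourse, "uptake_time_course"))

  geo <- tryCatch(internal_volume(config$assay, config$liposome),
                  error = function(e) .stopf("[geometry] %s", conditionMessage(e)))
  smry <- tryCatch(summarize_time_course(timecourse, config$plateau_n),
                   error = function(e) .stopf("[accumulation] %s", conditionMessage(e)))

  to_mol <- function(x) {
    if (attr(timecourse, "value_type") == "cpm")
      counts_to_moles(x, config$assay)
    else x * 1e-9               # nmol -> mol
  }
  c_peak <- internal_concentration(to_mol(smry$peak), geo$v_internal)
  c_plat <- internal_concentration(to_mol(smry$plateau), geo$v_internal)
  fold_peak <- fold_accumulation(c_peak, config$assay$external_conc)
  fold_plat <- fold_accumulation(c_plat, config$assay$external_conc)
  pheno <- classify_phenotype(fold_peak, fold_plat,
                              c_in_peak = c_peak, c_in_plateau = c_plat,
                              channel_threshold = config$thresholds$channel,
                              coupled_threshold = config$thresholds$coupled)
  structure(list(
    report_version = "1.0",
    geometry = list(
      n_lipids_per_liposome = .q(geo$n_lipids_per_liposome,
                                 "lipids/proteoliposome"),
      lipid_conc = .q(geo$lipid_conc, "mol/L"),
      n_liposomes_per_L = .q(geo$n_liposomes_per_L, "proteoliposomes/L"),
      n_liposomes_in_assay = .q(geo$n_liposomes_in_assay, "proteoliposomes"),
      v_internal = .q(geo$v_internal, "L"),
      v_internal_uL = .q(geo$v_internal_uL, "uL")),
    uptake = list(
      peak_amount = .q(smry$peak, attr(timecourse, "value_type")),
      peak_time = .q(smry$peak_time, "s"),
      plateau_amount = .q(smry$plateau, attr(timecourse, "value_type")),
      c_in_peak = .q(c_peak, "mM"),
      c_in_plateau = .q(c_plat, "mM"),
      external_conc = .q(config$assay$external_conc, "mM")),
    phenotype = pheno), class = "flux_report")
}

#' @export
print.flux_report <- function(x, ...) {
  g <- x$geometry; u <- x$uptake
  cat("Proteoliposome flux report (v", x$report_version, ")\n", sep = "")
  cat(sprintf("  lipids/vesicle   : %.2f\n", g$n_lipids_per_liposome$value))
  cat(sprintf("  vesicles/L       : %.4g\n", g$n_liposomes_per_L$value))
  cat(sprintf("  V_internal       : %.4g uL\n", g$v_internal_uL$value))
  cat(sprintf("  peak             : %.4g %s at %g s -> %.4g mM\n",
              u$peak_amount$value, u$peak_amount$unit, u$peak_time$value,
              u$c_in_peak$value))
  cat(sprintf("  plateau          : %.4g %s -> %.4g mM\n",
              u$plateau_amount$value, u$plateau_amount$unit,
              u$c_in_plateau$value))
  print(x$phenotype)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `flux_report` from [run_pipeline()].
#' @param path Output path; directories are created as needed.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "flux_report"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rep2 <- report
  rep2$phenotype <- unclass(rep2$phenotype)
  jsonlite::write_json(unclass(rep2), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
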