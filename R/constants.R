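# CODATA physical constants used throughout; kept in one place so every
# module shares identical values.
.CONST <- list(
  R    = 8.314462618,    # gas constant, J mol^-1 K^-1
  F    = 96485.33212,    # Faraday constant, C mol^-1
  N_A  = 6.02214076e23,  # Avogadro constant, mol^-1
  T_default = 298.15,    # K
  dpm_per_mCi = 2.22e9   # disintegrations per minute in one millicurie
)

#' Physical constants used by the package
#'
#' Returns the CODATA values of the gas constant, Faraday constant and
#' Avogadro constant, together with the default assay temperature (298.15 K)
#' and the radiochemical conversion factor (2.22e9 dpm per mCi).
#'
#' @return A named list with elements `R` (J mol^-1 K^-1), `F` (C mol^-1),
#'   `N_A` (mol^-1), `T_default` (K) and `dpm_per_mCi`.
#' @examples
#' physical_constants()$N_A
#' @export
physical_constants <- function() .CONST

# ---- centralized unit conversions ------------------------------------------
# All interface units are nm / uL / mg / ug / mM; SI (m, L, g, mol) is used
# internally. Every power of ten lives here.
.nm3_to_L  <- function(x) x * 1e-24
.uL_to_L   <- function(x) x * 1e-6
.L_to_uL   <- function(x) x * 1e6
.mg_to_g   <- function(x) x * 1e-3
.ug_to_mg  <- function(x) x * 1e-3
.mM_to_M   <- function(x) x * 1e-3
.M_to_mM   <- function(x) x * 1e3
.mmol_to_mol <- function(x) x * 1e-3

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                       len = 1L, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    .stopf("'%s' must be supplied", name)
  }
  if (!is.numeric(x) || (!is.na(len) && length(x) != len) || anyNA(x))
    .stopf("'%s' must be a non-missing numeric of length %s", name, len)
  if (positive && any(x <= 0)) .stopf("'%s' must be > 0", name)
  if (nonneg && any(x < 0)) .stopf("'%s' must be >= 0", name)
  invisible(x)
}
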