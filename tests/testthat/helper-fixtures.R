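# Reference assay fixture: a 100-nm extruded vesicle preparation, 4 uL of
# 5 mg/mL proteoliposomes in a 100 uL assay with 0.5 mM external substrate.
ref_liposome <- function() liposome_spec(r_outer = 50, m_membrane = 4,
                                         a_headgroup = 0.7, lipid_mw = 790.85)

ref_assay <- function(...) assay_spec(lipid_mass = 0.02, assay_volume = 100,
                                      external_conc = 0.5, ...)

# Independent brute-force arithmetic oracle for the geometry chain.
# Deliberately shares no code with the package: every step is spelled out
# in literal unit conversions.
geometry_oracle <- function(r_nm, m_nm, a_nm2, mw, lipid_mg, vol_uL) {
  avogadro <- 6.02214076e23
  outer_area_nm2 <- 4 * pi * r_nm * r_nm
  inner_area_nm2 <- 4 * pi * (r_nm - m_nm) * (r_nm - m_nm)
  lipids_per_vesicle <- (outer_area_nm2 + inner_area_nm2) / a_nm2
  grams_per_litre <- (lipid_mg / 1000) / (vol_uL / 1e6)
  mol_per_litre <- grams_per_litre / mw
  lipids_per_litre <- mol_per_litre * avogadro
  vesicles_per_litre <- lipids_per_litre / lipids_per_vesicle
  vesicles_in_assay <- vesicles_per_litre * (vol_uL / 1e6)
  lumen_radius_m <- (r_nm - m_nm) * 1e-9
  lumen_m3 <- 4 / 3 * pi * lumen_radius_m^3
  v_internal_L <- lumen_m3 * 1000 * vesicles_in_assay
  list(lipids_per_vesicle = lipids_per_vesicle,
       mol_per_litre = mol_per_litre,
       vesicles_per_litre = vesicles_per_litre,
       vesicles_in_assay = vesicles_in_assay,
       v_internal_L = v_internal_L)
}

# Closed-form OLS line fit (textbook formulas), independent of lm()
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}
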