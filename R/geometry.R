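#' Geometric description of a unilamellar proteoliposome
#'
#' Bundles the geometric and chemical parameters of a monodisperse
#' unilamellar vesicle preparation: the external radius, the bilayer
#' thickness, the area occupied by one lipid headgroup, and the average
#' molar mass of the lipids. These four numbers determine how many lipid
#' molecules build one vesicle and hence, together with the lipid mass in an
#' assay, how many vesicles the assay contains and what aqueous volume they
#' enclose.
#'
#' @param r_outer External vesicle radius in nm (50 nm for a nominal
#'   100-nm extruded vesicle).
#' @param m_membrane Bilayer thickness in nm (default 4 nm).
#' @param a_headgroup Area per lipid headgroup in nm^2 (default 0.7 nm^2,
#'   typical for phosphatidylcholine-rich membranes).
#' @param lipid_mw Average lipid molar mass in g/mol (default 790.85 g/mol
#'   for an E. coli polar lipid / POPC style mixture).
#' @return An object of class `liposome_spec`.
#' @examples
#' liposome_spec()                      # the default 100-nm vesicle
#' liposome_spec(r_outer = 25)          # a 50-nm vesicle
#' @export
liposome_spec <- function(r_outer = 50, m_membrane = 4,
                          a_headgroup = 0.7, lipid_mw = 790.85) {
  .check_num(r_outer, "r_outer", positive = TRUE)
  .check_num(m_membrane, "m_membrane", positive = TRUE)
  .check_num(a_headgroup, "a_headgroup", positive = TRUE)
  .check_num(lipid_mw, "lipid_mw", positive = TRUE)
  if (r_outer <= m_membrane)
    .stopf("invalid geometry: r_outer (%g nm) must exceed m_membrane (%g nm)",
           r_outer, m_membrane)
  structure(list(r_outer = r_outer, m_membrane = m_membrane,
                 a_headgroup = a_headgroup, lipid_mw = lipid_mw),
            class = "liposome_spec")
}

#' @export
print.liposome_spec <- function(x, ...) {
  cat("Liposome spec: r_outer =", x$r_outer, "nm, bilayer =", x$m_membrane,
      "nm, headgroup area =", x$a_headgroup, "nm^2, lipid MW =",
      x$lipid_mw, "g/mol\n")
  invisible(x)
}

#' Composition of one flux assay
#'
#' Describes a single proteoliposome uptake assay: how much lipid it
#' contains, its total volume, the external substrate concentration, and
#' (optionally) the radiochemistry and protein content needed to convert
#' raw counts to moles and rates to specific activities.
#'
#' @param lipid_mass Lipid mass in the assay, mg (e.g. 4 uL of a 5 mg/mL
#'   proteoliposome stock in a 100 uL assay is 0.02 mg).
#' @param assay_volume Total assay volume, uL.
#' @param external_conc External substrate concentration, mM.
#' @param specific_activity Optional radiolabel specific activity, mCi/mmol.
#' @param counting_efficiency Optional scintillation counting efficiency,
#'   a fraction in (0, 1].
#' @param protein_mass Optional reconstituted protein mass in the assay, ug.
#' @return An object of class `assay_spec`.
#' @examples
#' assay_spec(lipid_mass = 0.02, assay_volume = 100, external_conc = 0.5)
#' @export
assay_spec <- function(lipid_mass, assay_volume, external_conc,
                       specific_activity = NULL, counting_efficiency = NULL,
                       protein_mass = NULL) {
  .check_num(lipid_mass, "lipid_mass", nonneg = TRUE)
  .check_num(assay_volume, "assay_volume", positive = TRUE)
  .check_num(external_conc, "external_conc", nonneg = TRUE)
  .check_num(specific_activity, "specific_activity", positive = TRUE,
             allow_null = TRUE)
  .check_num(counting_efficiency, "counting_efficiency", allow_null = TRUE)
  if (!is.null(counting_efficiency) &&
      (counting_efficiency <= 0 || counting_efficiency > 1))
    .stopf("'counting_efficiency' must lie in (0, 1]")
  .check_num(protein_mass, "protein_mass", positive = TRUE, allow_null = TRUE)
  structure(list(lipid_mass = lipid_mass, assay_volume = assay_volume,
                 external_conc = external_conc,
                 specific_activity = specific_activity,
                 counting_efficiency = counting_efficiency,
                 protein_mass = protein_mass),
            class = "assay_spec")
}

#' @export
print.assay_spec <- function(x, ...) {
  cat("Assay:", x$lipid_mass, "mg lipid in", x$assay_volume,
      "uL, external substrate", x$external_conc, "mM\n")
  if (!is.null(x$specific_activity))
    cat("  specific activity:", x$specific_activity, "mCi/mmol\n")
  if (!is.null(x$protein_mass))
    cat("  protein:", x$protein_mass, "ug\n")
  invisible(x)
}

#' Lipid molecules per proteoliposome
#'
#' Counts the lipid molecules needed to build one unilamellar vesicle as the
#' summed areas of the outer and inner monolayer spheres divided by the area
#' per headgroup:
#' \deqn{N_{tot} = \frac{4\pi r^2 + 4\pi (r-m)^2}{a}}
#' where `r` is the external radius, `m` the bilayer thickness and `a` the
#' headgroup area. The inner monolayer is evaluated at radius `r - m`.
#'
#' @param spec A [liposome_spec()].
#' @return Number of lipids per vesicle (dimensionless count).
#' @examples
#' lipids_per_liposome(liposome_spec())   # ~82,866 for the 100-nm vesicle
#' @export
lipids_per_liposome <- function(spec) {
  stopifnot(inherits(spec, "liposome_spec"))
  r <- spec$r_outer
  ri <- r - spec$m_membrane
  (4 * pi * r^2 + 4 * pi * ri^2) / spec$a_headgroup
}

#' Molar lipid concentration of an assay
#'
#' Converts the lipid mass and assay volume into a molar lipid
#' concentration using the average lipid molar mass:
#' g lipid per litre divided by g/mol.
#'
#' @param assay An [assay_spec()].
#' @param spec A [liposome_spec()] supplying the average lipid molar mass.
#' @return Lipid concentration in mol/L.
#' @examples
#' lipid_molar_concentration(
#'   assay_spec(0.02, 100, 0.5), liposome_spec())  # 2.53e-4 M
#' @export
lipid_molar_concentration <- function(assay, spec) {
  stopifnot(inherits(assay, "assay_spec"), inherits(spec, "liposome_spec"))
  g_per_L <- .mg_to_g(assay$lipid_mass) / .uL_to_L(assay$assay_volume)
  g_per_L / spec$lipid_mw
}

#' Number of proteoliposomes in an assay
#'
#' Divides the number of lipid molecules per litre (molar lipid
#' concentration times the Avogadro constant) by the number of lipids per
#' vesicle, and scales by the assay volume for the per-assay count.
#'
#' @inheritParams lipid_molar_concentration
#' @return A list with `per_L` (vesicles per litre) and `in_assay`
#'   (vesicles in the assay volume).
#' @examples
#' liposome_count(assay_spec(0.02, 100, 0.5), liposome_spec())
#' @export
liposome_count <- function(assay, spec) {
  lipids_per_L <- lipid_molar_concentration(assay, spec) * .CONST$N_A
  per_L <- lipids_per_L / lipids_per_liposome(spec)
  list(per_L = per_L, in_assay = per_L * .uL_to_L(assay$assay_volume))
}

#' Total intraliposomal volume of an assay
#'
#' Computes the complete geometric chain for a proteoliposome assay: lipids
#' per vesicle, molar lipid concentration, vesicle counts, and the total
#' enclosed aqueous volume
#' \deqn{V_{PL} = \tfrac{4}{3}\pi (r-m)^3 \times N_{PL}}
#' where the inner radius `r - m` defines the aqueous lumen of one vesicle
#' and `N_{PL}` is the vesicle count in the assay. This volume converts
#' accumulated moles of substrate into an internal concentration.
#'
#' @inheritParams lipid_molar_concentration
#' @return An object of class `geometry_result` with fields
#'   `n_lipids_per_liposome`, `lipid_conc` (mol/L), `n_liposomes_per_L`,
#'   `n_liposomes_in_assay`, `v_internal` (L) and `v_internal_uL`.
#' @examples
#' internal_volume(assay_spec(0.02, 100, 0.5), liposome_spec())
#' @export
internal_volume <- function(assay, spec) {
  n_tot <- lipids_per_liposome(spec)
  conc <- lipid_molar_concentration(assay, spec)
  counts <- liposome_count(assay, spec)
  ri <- spec$r_outer - spec$m_membrane
  v_one <- .nm3_to_L(4 / 3 * pi * ri^3)
  v_int <- v_one * counts$in_assay
  structure(list(n_lipids_per_liposome = n_tot,
                 lipid_conc = conc,
                 n_liposomes_per_L = counts$per_L,
                 n_liposomes_in_assay = counts$in_assay,
                 v_internal = v_int,
                 v_internal_uL = .L_to_uL(v_int)),
            class = "geometry_result")
}

#' @export
print.geometry_result <- function(x, ...) {
  cat("Proteoliposome geometry\n")
  cat(sprintf("  lipids per vesicle      : %.2f\n", x$n_lipids_per_liposome))
  cat(sprintf("  lipid concentration     : %.4g mol/L\n", x$lipid_conc))
  cat(sprintf("  vesicles per litre      : %.4g\n", x$n_liposomes_per_L))
  cat(sprintf("  vesicles in assay       : %.4g\n", x$n_liposomes_in_assay))
  cat(sprintf("  intraliposomal volume   : %.4g L (%.4g uL)\n",
              x$v_internal, x$v_internal_uL))
  invisible(x)
}
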