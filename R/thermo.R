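#' Physical constants of the hydration model
#'
#' Bundles the constants the hydration free-energy model needs: the Gibbs
#' free energy of a tetrahedral (double donor-double acceptor, DDAA)
#' hydrogen-bonding configuration, the Gibbs free energy of bulk water, the
#' effective water radius, and the thermodynamic state (temperature,
#' pressure). All energies are stored internally in kJ/mol; the bulk-water
#' term is commonly tabulated in cal/mol and can be supplied that way.
#'
#' @param dG_DDAA Gibbs free energy of tetrahedral hydrogen bonding,
#'   kJ/mol. Negative (bond formation is favourable). Default -2.66.
#' @param dG_water_water Gibbs free energy of bulk water. Interpreted in
#'   the unit named by `dG_water_water_unit`. Default -1500 cal/mol.
#' @param dG_water_water_unit `"cal/mol"` (default) or `"kJ/mol"`.
#' @param r_H2O effective radius of a water molecule, Angstrom. Default
#'   1.9, the spherical-equivalent radius of a 3e-29 m^3 molecular volume
#'   (see [spherical_radius_from_volume()]).
#' @param T_K temperature, K. @param P_MPa pressure, MPa.
#'
#' @return An object of class `thermo_constants`: a list with elements
#'   `dG_DDAA`, `dG_water_water` (both kJ/mol), `r_H2O` (Angstrom), `T_K`,
#'   `P_MPa`.
#' @examples
#' tc <- thermo_constants()
#' critical_radius(tc)
#' @export
thermo_constants <- function(dG_DDAA = -2.66,
                             dG_water_water = -1500,
                             dG_water_water_unit = c("cal/mol", "kJ/mol"),
                             r_H2O = 1.9,
                             T_K = 293,
                             P_MPa = 0.1) {
  dG_water_water_unit <- match.arg(dG_water_water_unit)
  if (!is.finite(r_H2O) || r_H2O <= 0) .stop_domain("'r_H2O' must be > 0")
  if (!is.finite(T_K) || T_K <= 0) .stop_domain("'T_K' must be > 0")
  if (dG_water_water_unit == "cal/mol") {
    dG_water_water <- dG_water_water * .CAL_TO_J / 1000
  }
  if (sign(dG_DDAA) * sign(dG_water_water) < 0) {
    warning("dG_DDAA and dG_water_water carry opposite signs; ",
            "the model expects a common sign convention (both negative)")
  }
  structure(
    list(dG_DDAA = dG_DDAA, dG_water_water = dG_water_water,
         r_H2O = r_H2O, T_K = T_K, P_MPa = P_MPa),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Hydration model constants\n")
  cat(sprintf("  dG_DDAA        : %8.3f kJ/mol\n", x$dG_DDAA))
  cat(sprintf("  dG_water_water : %8.3f kJ/mol\n", x$dG_water_water))
  cat(sprintf("  r_H2O          : %8.2f Angstrom\n", x$r_H2O))
  cat(sprintf("  T, P           : %g K, %g MPa\n", x$T_K, x$P_MPa))
  invisible(x)
}

.check_constants <- function(constants) {
  if (!inherits(constants, "thermo_constants"))
    .stop_domain("'constants' must be created by thermo_constants()")
  constants
}

#' Spherical-equivalent radius of a molecular volume
#'
#' Radius of the sphere with the given volume, `(3 V / 4 pi)^(1/3)`,
#' converted from m^3 to Angstrom. Applied to the ambient molecular volume
#' of water (about 3e-29 m^3) it yields the effective water radius of
#' roughly 1.9 Angstrom used throughout the hydration model.
#'
#' @param volume_m3 molecular volume in m^3; must be positive.
#' @return radius in Angstrom.
#' @examples
#' spherical_radius_from_volume(3e-29) # ~1.9
#' @export
spherical_radius_from_volume <- function(volume_m3) {
  if (any(!is.finite(volume_m3)) || any(volume_m3 <= 0))
    .stop_domain("'volume_m3' must be positive and finite")
  (3 * volume_m3 / (4 * pi))^(1 / 3) * 1e10
}

#' Interfacial-to-volume water ratio of a spherical solute
#'
#' For a sphere of radius `R`, the molecular-number ratio of the top
#' (interfacial) water layer to volume is `4 r_H2O / R`.
#'
#' @param R solute radius, Angstrom; positive.
#' @param constants a [thermo_constants()] object (supplies `r_H2O`).
#' @return dimensionless ratio.
#' @export
interfacial_volume_ratio_sphere <- function(R, constants = thermo_constants()) {
  .check_constants(constants)
  if (any(!is.finite(R)) || any(R <= 0)) .stop_domain("'R' must be > 0")
  4 * constants$r_H2O / R
}

#' Solute-water free energy of a spherical solute
#'
#' Free-energy cost attributed to the interfacial water layer: the DDAA
#' bond free energy times the interfacial-to-volume ratio times the number
#' of hydrogen bonds lost per interfacial molecule,
#' `dG_DDAA * (4 r_H2O / R) * n_HB`. With the default `n_HB = 2` this is
#' the `8 dG_DDAA r_H2O / R` term of the hydration free energy.
#'
#' @inheritParams interfacial_volume_ratio_sphere
#' @param n_HB hydrogen bonds lost per interfacial molecule; non-negative.
#'   Default 2 (tetrahedral bonding loses two of four bond-ends at a
#'   flat-cut interface).
#' @return kJ/mol.
#' @export
solute_water_free_energy <- function(R, constants = thermo_constants(),
                                     n_HB = 2) {
  .check_constants(constants)
  if (any(!is.finite(R)) || any(R <= 0)) .stop_domain("'R' must be > 0")
  if (!is.finite(n_HB) || n_HB < 0) .stop_domain("'n_HB' must be >= 0")
  constants$dG_DDAA * interfacial_volume_ratio_sphere(R, constants) * n_HB
}

#' Hydration free energy of a spherical solute
#'
#' Sum of the bulk-water term and the size-dependent interfacial term:
#' `dG_water_water + 8 dG_DDAA r_H2O / R`. The interfacial term decays as
#' 1/R, so the profile converges to the bulk value for large solutes and
#' is dominated by the interface for small ones; the crossover radius is
#' [critical_radius()].
#'
#' @inheritParams interfacial_volume_ratio_sphere
#' @return kJ/mol (vectorised over `R`).
#' @examples
#' tc <- thermo_constants()
#' hydration_free_energy(c(2, 6.5, 50), tc)
#' @export
hydration_free_energy <- function(R, constants = thermo_constants()) {
  .check_constants(constants)
  if (any(!is.finite(R)) || any(R <= 0)) .stop_domain("'R' must be > 0")
  constants$dG_water_water + solute_water_free_energy(R, constants, n_HB = 2)
}

#' Critical solute radius
#'
#' The radius at which the interfacial (solute-water) and bulk
#' (water-water) free-energy terms of the hydration model balance:
#' `Rc = 8 |dG_DDAA| r_H2O / |dG_water_water|`. Both constants are
#' negative under the model's sign convention, so the ratio is taken on
#' magnitudes and the returned radius is positive. Below `Rc` hydration is
#' dominated by the interfacial term (initial solvation); above it by the
#' bulk term (hydrophobic solvation).
#'
#' @inheritParams interfacial_volume_ratio_sphere
#' @return critical radius in Angstrom.
#' @examples
#' critical_radius(thermo_constants()) # ~6.44, i.e. 6.4 Angstrom
#' @export
critical_radius <- function(constants = thermo_constants()) {
  .check_constants(constants)
  if (constants$dG_water_water == 0)
    .stop_domain("'dG_water_water' must be non-zero")
  8 * abs(constants$dG_DDAA) * constants$r_H2O / abs(constants$dG_water_water)
}

#' Geometric factor of solute aggregation
#'
#' Ratio of the aggregated to the non-aggregated surface-area-to-volume
#' ratio. It equals 1 while the solute separation exceeds the hydrophobic
#' radius `R_H` (surfaces not in contact; no interfacial area lost) and
#' drops below 1 once surfaces touch.
#'
#' @param sa_over_v_aggregate surface-area-to-volume ratio of the
#'   aggregated state, 1/Angstrom; positive.
#' @param sa_over_v_separate surface-area-to-volume ratio of the separated
#'   (non-aggregated) state, 1/Angstrom; positive.
#' @param r_separation solute-solute separation, Angstrom; non-negative.
#' @param R_H hydrophobic radius: the separation at which surfaces first
#'   make contact, Angstrom.
#' @return dimensionless factor in (0, 1] for physically sensible inputs;
#'   exactly 1 whenever `r_separation > R_H`.
#' @export
geometric_factor <- function(sa_over_v_aggregate, sa_over_v_separate,
                             r_separation, R_H) {
  if (!is.finite(sa_over_v_aggregate) || sa_over_v_aggregate <= 0 ||
      !is.finite(sa_over_v_separate) || sa_over_v_separate <= 0)
    .stop_domain("surface-area-to-volume ratios must be > 0")
  if (!is.finite(r_separation) || r_separation < 0)
    .stop_domain("'r_separation' must be >= 0")
  if (r_separation > R_H) return(1)
  sa_over_v_aggregate / sa_over_v_separate
}

#' Hydrophobic interaction energy from interfacial-to-bulk transitions
#'
#' The strength of the hydrophobic interaction accumulated during solute
#' association is proportional to the number of water molecules that leave
#' the interfacial layer for the bulk, each contributing one tetrahedral
#' bond free energy: `n * dG_DDAA`.
#'
#' @param n_transferred count of interfacial-to-bulk molecules;
#'   non-negative integer(s).
#' @param constants a [thermo_constants()] object.
#' @return kJ/mol (vectorised over `n_transferred`).
#' @export
hydrophobic_interaction_energy <- function(n_transferred,
                                           constants = thermo_constants()) {
  .check_constants(constants)
  if (any(!is.finite(n_transferred)) || any(n_transferred < 0) ||
      any(n_transferred != round(n_transferred)))
    .stop_domain("'n_transferred' must be non-negative integer(s)")
  n_transferred * constants$dG_DDAA
}

#' Aggregate shape from the molecular packing parameter
#'
#' Computes the packing parameter `p = v0 / (a_head * l0)` of an
#' amphiphile and maps it to the equilibrium aggregate shape through the
#' classical intervals: `[0, 1/3]` sphere, `(1/3, 1/2]` cylinder,
#' `(1/2, 1]` bilayer, above 1 out-of-range. The printed intervals overlap
#' at 1/3 and 1/2; boundary values are assigned to the smaller-curvature
#' class on the left (closed-left convention) so the map is deterministic.
#'
#' @param v0 surfactant tail volume, Angstrom^3; positive.
#' @param a_head surface area per molecule of the aggregate's hydrophobic
#'   core, Angstrom^2; positive.
#' @param l0 tail length, Angstrom; positive.
#' @return a list with `p` (the packing parameter) and `shape`, one of
#'   `"sphere"`, `"cylinder"`, `"bilayer"`, `"out-of-range"`.
#' @examples
#' packing_parameter_shape(v0 = 350, a_head = 60, l0 = 17)
#' @export
packing_parameter_shape <- function(v0, a_head, l0) {
  if (any(!is.finite(c(v0, a_head, l0))) || any(c(v0, a_head, l0) <= 0))
    .stop_domain("'v0', 'a_head' and 'l0' must all be > 0")
  p <- v0 / (a_head * l0)
  shape <-
    if (p <= 1 / 3) "sphere"
    else if (p <= 1 / 2) "cylinder"
    else if (p <= 1) "bilayer"
    else "out-of-range"
  list(p = p, shape = shape)
}
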