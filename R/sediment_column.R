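# 1-m discretized sediment columns: Athy-type compaction, depth integration
# of volumetric production to areal rates, and linear depth-to-age models.

#' Construct a sediment column
#'
#' A column is a homogeneous (lithology constant with depth) stack of
#' sediment characterized by its thickness, seafloor porosity, grain density
#' and bulk radionuclide composition. Layered columns for the transport model
#' are handled separately by [two_layer_profile()]/[numeric_profile()].
#'
#' @param lithology lithology category (must exist in the yield table).
#' @param thickness_m sediment thickness Z, m.
#' @param water_depth_m water depth, m (selects the compaction coefficient).
#' @param phi0 seafloor porosity fraction, in (0, 1).
#' @param rho grain density, g cm-3.
#' @param composition an [elemental_composition()].
#' @param basement_age_Ma basement age, Ma (needed for depth-to-age).
#' @return object of class `sediment_column`.
#' @export
sediment_column <- function(lithology, thickness_m, water_depth_m, phi0, rho,
                            composition, basement_age_Ma = NA_real_) {
  if (thickness_m < 0) stop("thickness_m must be >= 0")
  if (!(phi0 > 0 && phi0 < 1)) stop("phi0 must lie in (0, 1)")
  if (rho <= 0) stop("rho must be > 0")
  stopifnot(inherits(composition, "elemental_composition"))
  structure(list(lithology = lithology, thickness_m = thickness_m,
                 water_depth_m = water_depth_m, phi0 = phi0, rho = rho,
                 composition = composition,
                 basement_age_Ma = basement_age_Ma),
            class = "sediment_column")
}

#' Compaction coefficient from water depth
#'
#' Porosity e-folding constants (per metre) by water-depth class:
#' continental shelf (0-200 m) 0.5e-3, continental margin (200-2500 m)
#' 1.7e-3, abyssal (>3500 m) 0.85e-3. The 2500-3500 m band is not covered by
#' the printed classes and is assigned the abyssal value (overridable by
#' supplying c0 directly to [porosity_at()]).
#'
#' @param water_depth_m water depth, m; vectorized.
#' @return c0, per metre.
#' @export
compaction_coefficient <- function(water_depth_m) {
  if (any(water_depth_m < 0)) stop("water_depth_m must be >= 0")
  ifelse(water_depth_m < 200, 0.5e-3,
         ifelse(water_depth_m < 2500, 1.7e-3, 0.85e-3))
}

#' Porosity at depth (Athy-type exponential compaction)
#'
#' phi(z) = phi0 * exp(-c0 z); non-increasing in z.
#'
#' @param phi0 seafloor porosity fraction.
#' @param c0 compaction coefficient, per metre.
#' @param z_m depth below seafloor, m; vectorized.
#' @export
porosity_at <- function(phi0, c0, z_m) {
  stopifnot(phi0 > 0, phi0 < 1, all(z_m >= 0))
  phi0 * exp(-c0 * z_m)
}

#' Depth-integrate a column's radiolytic production
#'
#' Evaluates the volumetric production rate in 1-m intervals (porosity taken
#' at each interval midpoint) and sums to an areal rate. Integration halts at
#' the base of the column or at the first depth where porosity reaches 0.1%
#' (phi <= 0.001), whichever comes first; the halt is flagged in the result.
#'
#' @param col a [sediment_column()].
#' @param energies,yields constant tables (overridable).
#' @param dz_m integration step, m (default 1).
#' @param phi_min porosity halt threshold (default 0.001).
#' @return list: `areal_eeq_mol_cm2_yr`, `areal_H2_mol_cm2_yr`, `profile`
#'   (data.frame z_m, phi, P_molecules_cm3_yr, P_eeq_mol_cm3_yr),
#'   `halted_by_porosity`.
#' @export
integrate_column <- function(col, energies = energy_partition(),
                             yields = yield_table(), dz_m = 1,
                             phi_min = 0.001) {
  stopifnot(inherits(col, "sediment_column"))
  Z <- col$thickness_m
  empty <- list(areal_eeq_mol_cm2_yr = 0, areal_H2_mol_cm2_yr = 0,
                profile = data.frame(z_m = numeric(0), phi = numeric(0),
                                     P_molecules_cm3_yr = numeric(0),
                                     P_eeq_mol_cm3_yr = numeric(0)),
                halted_by_porosity = FALSE)
  if (Z <= 0) return(empty)
  c0 <- compaction_coefficient(col$water_depth_m)
  z <- seq(dz_m / 2, Z, by = dz_m)                      # interval midpoints
  phi <- porosity_at(col$phi0, c0, z)
  halted <- any(phi <= phi_min)
  if (halted) {
    keep <- phi > phi_min
    z <- z[keep]; phi <- phi[keep]
    if (!length(z)) return(utils::modifyList(empty, list(halted_by_porosity = TRUE)))
  }
  acts <- activities(isotope_abundances(col$composition))
  p <- production_rate(acts, col$rho, phi, col$lithology, energies, yields)
  dz_cm <- dz_m * 100
  list(
    areal_eeq_mol_cm2_yr = sum(p$eeq_mol_cm3_yr) * dz_cm,
    areal_H2_mol_cm2_yr  = sum(p$mol_cm3_yr) * dz_cm,
    profile = data.frame(z_m = z, phi = phi,
                         P_molecules_cm3_yr = p$molecules_cm3_yr,
                         P_eeq_mol_cm3_yr = p$eeq_mol_cm3_yr),
    halted_by_porosity = halted
  )
}

#' Convert sediment depth to age with a mean-accumulation-rate model
#'
#' Mean accumulation rate = thickness / basement age; age(z) = z / rate,
#' linear in z, mapping [0, Z] onto [0, basement age].
#'
#' @param z_m depth below seafloor, m; vectorized.
#' @param col a [sediment_column()] with `basement_age_Ma` set.
#' @return age, Ma.
#' @export
depth_to_age <- function(z_m, col) {
  stopifnot(inherits(col, "sediment_column"))
  if (is.na(col$basement_age_Ma) || col$basement_age_Ma <= 0)
    stop("basement_age_Ma must be > 0 for age conversion")
  if (col$thickness_m == 0) {
    if (any(z_m > 0)) stop("column has zero thickness but z_m > 0")
    return(rep(0, length(z_m)))
  }
  if (any(z_m < 0 | z_m > col$thickness_m))
    stop("z_m must lie within [0, thickness_m]")
  z_m / (col$thickness_m / col$basement_age_Ma)
}
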