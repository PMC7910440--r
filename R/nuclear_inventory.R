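# Radionuclide inventories: bulk U/Th/K -> per-isotope activities and
# chain-summed decay-energy partitions at secular equilibrium.

.radH2 <- new.env(parent = emptyenv())

#' Physical constants used throughout the package
#'
#' @format Named list: Avogadro's number (`NA_mol`), seconds per Julian year
#'   (`sec_per_yr`), gas constant in kJ mol-1 K-1 (`R_kJ`), authalic Earth
#'   radius in km (`R_earth_km`), molar masses of K and K2O (g mol-1).
#' @export
radh2_constants <- list(
  NA_mol      = 6.02214076e23,
  sec_per_yr  = 3.15576e7,
  R_kJ        = 8.314e-3,
  R_earth_km  = 6371.0,
  M_K         = 39.0983,
  M_K2O       = 94.1960
)

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "radH2")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  path
}

#' Packaged nuclide constants
#'
#' Isotopic abundances, atomic masses, half-lives, and decay-series energy
#' partitions (alpha/beta/gamma, MeV per parent decay, summed over each chain
#' at secular equilibrium). Beta energies are mean emitted kinetic energies;
#' energy carried by antineutrinos is excluded since it is not deposited in
#' the sediment. Values are standard literature constants (the provenance
#' column documents each row) and can be overridden by supplying a data frame
#' of the same shape to the functions that take a `constants` argument.
#'
#' @param path optional path to a replacement CSV with the same columns.
#' @return data.frame with one row per isotope (U238, U235, Th232, K40).
#' @export
nuclide_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.radH2$nuclides)) {
      .radH2$nuclides <- utils::read.csv(.extdata("nuclide_constants.csv"),
                                         stringsAsFactors = FALSE)
    }
    return(.radH2$nuclides)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bulk elemental composition of sediment
#'
#' Holds measured total U, Th (ppm of solid) and potassium content. Potassium
#' may be given either as K2O weight percent (the form reported by ICP-ES) or
#' directly as K weight percent; the K2O -> K molar-mass conversion
#' (2 M_K / M_K2O = 0.83015) is applied exactly once, here.
#'
#' @param U_ppm total uranium, micrograms per gram of dry solid.
#' @param Th_ppm total thorium, micrograms per gram of dry solid.
#' @param K2O_wt_pct K2O weight percent of the solid (alternative to K_wt_pct).
#' @param K_wt_pct K weight percent of the solid.
#' @return object of class `elemental_composition`.
#' @export
elemental_composition <- function(U_ppm, Th_ppm, K2O_wt_pct = NULL, K_wt_pct = NULL) {
  if (is.null(K2O_wt_pct) == is.null(K_wt_pct))
    stop("supply exactly one of K2O_wt_pct or K_wt_pct")
  if (is.null(K_wt_pct)) {
    if (K2O_wt_pct < 0) stop("K2O_wt_pct must be >= 0")
    K_wt_pct <- K2O_wt_pct * 2 * radh2_constants$M_K / radh2_constants$M_K2O
  }
  vals <- c(U_ppm = U_ppm, Th_ppm = Th_ppm, K_wt_pct = K_wt_pct)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("composition values must be finite and >= 0")
  structure(as.list(vals), class = "elemental_composition")
}

#' Per-isotope mass concentrations from a bulk composition
#'
#' Multiplies each elemental concentration by the packaged isotopic abundance
#' (Th232 abundance is 1; natural U is split between 238U and 235U; 40K is a
#' trace fraction of K). Result is in micrograms of isotope per gram of solid.
#'
#' @param comp an `elemental_composition`.
#' @param constants nuclide constant table, see [nuclide_constants()].
#' @return named numeric vector (U238, U235, Th232, K40), ug/g solid.
#' @export
isotope_abundances <- function(comp, constants = nuclide_constants()) {
  stopifnot(inherits(comp, "elemental_composition"))
  ab <- stats::setNames(constants$abundance, constants$isotope)
  elem_ug_g <- c(U = comp$U_ppm, Th = comp$Th_ppm, K = comp$K_wt_pct * 1e4)
  out <- c(
    U238  = unname(elem_ug_g["U"]  * ab["U238"]),
    U235  = unname(elem_ug_g["U"]  * ab["U235"]),
    Th232 = unname(elem_ug_g["Th"] * ab["Th232"]),
    K40   = unname(elem_ug_g["K"]  * ab["K40"])
  )
  out
}

#' Activities from per-isotope concentrations
#'
#' A = lambda N with lambda = ln(2)/half-life and N the number of atoms per
#' gram of solid (Avogadro's number / atomic mass). Activities are linear in
#' the parent concentration; secular equilibrium of each decay series is
#' assumed so the whole chain's energy release scales with the parent
#' activity.
#'
#' @param iso_ug_g named numeric vector as returned by [isotope_abundances()].
#' @param constants nuclide constant table.
#' @return object of class `isotope_activity`: named vector, decays yr-1 g-1
#'   solid.
#' @export
activities <- function(iso_ug_g, constants = nuclide_constants()) {
  unknown <- setdiff(names(iso_ug_g), constants$isotope)
  if (length(unknown)) stop("unknown isotope(s): ", paste(unknown, collapse = ", "))
  if (any(iso_ug_g < 0)) stop("isotope concentrations must be >= 0")
  idx <- match(names(iso_ug_g), constants$isotope)
  lambda <- log(2) / constants$half_life_yr[idx]           # yr-1
  N <- iso_ug_g * 1e-6 / constants$atomic_mass[idx] * radh2_constants$NA_mol
  structure(lambda * N, class = "isotope_activity")
}

#' Convert activities between decays yr-1 g-1 and Bq kg-1
#'
#' @param a activity in decays yr-1 g-1 (or Bq kg-1 for the inverse).
#' @return numeric of the same length.
#' @export
activity_to_Bq_kg <- function(a) unclass(a) * 1e3 / radh2_constants$sec_per_yr

#' @rdname activity_to_Bq_kg
#' @export
Bq_kg_to_activity <- function(a) unclass(a) * radh2_constants$sec_per_yr / 1e3

#' Decay-energy partition of each series
#'
#' Energy emitted per parent decay as alpha, beta and gamma radiation, summed
#' over the full decay chain at secular equilibrium (MeV per decay). 40K has
#' no alpha branch, so its alpha entry is exactly zero. These are packaged
#' constants, invariant to any concentration input.
#'
#' @param constants nuclide constant table.
#' @return data.frame with rows U238, U235, Th232, K40 and columns
#'   alpha/beta/gamma (MeV per parent decay).
#' @export
energy_partition <- function(constants = nuclide_constants()) {
  data.frame(
    row.names = constants$isotope,
    alpha = constants$E_alpha_MeV,
    beta  = constants$E_beta_MeV,
    gamma = constants$E_gamma_MeV
  )
}

#' Read a site composition table
#'
#' Expected columns: site, depth_m, U_ppm, Th_ppm, K2O_wt_pct.
#'
#' @param path CSV path.
#' @return data.frame; a named validation error is raised if a required
#'   column is missing.
#' @export
read_composition_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "depth_m", "U_ppm", "Th_ppm", "K2O_wt_pct")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("composition table missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}
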