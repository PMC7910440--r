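# Volumetric radiolytic H2 production, the lithology-specific yield table,
# stoichiometric oxidant production, and electron-equivalent conversions.
#
# The production model is
#   P_H2 = sum_i sum_s A_{m,s} * rho * (1 - phi) * E_{s,i} * G(H2)_i
# over radiation types i (alpha, beta, gamma) and parent series s
# (238U, 235U, 232Th chains, 40K), with A_m the activity per mass of solid,
# E the chain-summed decay energy per parent decay, and G(H2) the radiolytic
# yield in molecules per 100 eV absorbed. The eV -> "per 100 eV" scaling is
# applied at exactly one site, inside production_rate().

#' Electron-equivalent factors
#'
#' Redox currency: 2 electrons per H2, 4 per O2, 4 per organic C oxidized.
#' @export
eeq_factors <- c(H2 = 2L, O2 = 4L, organic_C = 4L)

#' Convert a molar species rate to electron equivalents
#'
#' @param rate molar rate (any volume/time basis).
#' @param species one of `names(eeq_factors)`.
#' @return rate in mol electron equivalents on the same basis.
#' @export
to_electron_equivalents <- function(rate, species) {
  species <- match.arg(species, names(eeq_factors))
  rate * as.numeric(eeq_factors[[species]])
}

#' Packaged radiolytic yield table
#'
#' G(H2) (molecules per 100 eV absorbed) by medium and radiation type.
#' Sediment-slurry yields exceed the pure-water yields for every medium; only
#' lithology means are recoverable from the printed amplification factors, so
#' the table stores means (per-sample rows are absent, flagged in the
#' provenance). Seawater yields are indistinguishable from pure water.
#' No beta rows are stored: beta queries resolve to the gamma entry
#' (see [yield_lookup()]).
#'
#' @param path optional replacement CSV (columns medium, radiation, G_mean,
#'   G_sd, G_max, n_samples, provenance).
#' @return data.frame.
#' @export
yield_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.radH2$yields)) {
      .radH2$yields <- utils::read.csv(.extdata("radiolytic_yields.csv"),
                                       stringsAsFactors = FALSE)
    }
    return(.radH2$yields)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up a G(H2) yield
#'
#' Beta yields have not been measured for water-saturated media; a beta query
#' returns the gamma entry for the same medium (the model's stated
#' substitution rule). Alpha and gamma return measured lithology means.
#'
#' @param table yield table, see [yield_table()].
#' @param medium e.g. "abyssal_clay", "pure_water".
#' @param radiation "alpha", "beta" or "gamma".
#' @return G value, molecules per 100 eV.
#' @export
yield_lookup <- function(table = yield_table(), medium, radiation) {
  radiation <- match.arg(radiation, c("alpha", "beta", "gamma"))
  lookup_rad <- if (radiation == "beta") "gamma" else radiation
  row <- table[table$medium == medium & table$radiation == lookup_rad, ]
  if (nrow(row) == 0)
    stop("no yield for medium '", medium, "', radiation '", radiation,
         "' in the yield table")
  row$G_mean[[1]]
}

#' Volumetric radiolytic H2 production rate
#'
#' Evaluates the production sum for a solid of grain density `rho` at
#' porosity `phi`, for the yield set of `medium`. `phi` may be a vector
#' (e.g. a porosity-depth profile); the result is vectorized accordingly.
#'
#' @param acts `isotope_activity` (decays yr-1 g-1 solid).
#' @param rho grain density, g cm-3.
#' @param phi porosity fraction in [0, 1]; vectorized.
#' @param medium lithology/medium name present in the yield table.
#' @param energies decay-energy partition, see [energy_partition()].
#' @param yields yield table.
#' @param beta_G optional override of the beta-radiation G value (used for
#'   the beta-assumption sensitivity analysis).
#' @return object of class `production_rate`: list with vectors
#'   `molecules_cm3_yr`, `mol_cm3_yr`, `eeq_mol_cm3_yr` (per cm3 of bulk
#'   sediment) and the per-radiation breakdown `by_radiation`
#'   (molecules cm-3 yr-1 at phi = 0, i.e. per unit (1 - phi)).
#' @export
production_rate <- function(acts, rho, phi, medium,
                            energies = energy_partition(),
                            yields = yield_table(),
                            beta_G = NULL) {
  stopifnot(inherits(acts, "isotope_activity"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  if (rho <= 0) stop("rho must be > 0")
  iso <- names(acts)
  if (!all(iso %in% rownames(energies)))
    stop("activities and energy partition name different isotopes")
  E <- energies[iso, , drop = FALSE]                    # MeV per decay
  G <- c(alpha = yield_lookup(yields, medium, "alpha"),
         beta  = if (is.null(beta_G)) yield_lookup(yields, medium, "beta") else beta_G,
         gamma = yield_lookup(yields, medium, "gamma"))
  # molecules per g solid per yr, by radiation type; the single eV -> 100 eV
  # conversion site: E [MeV] * 1e6 [eV/MeV] * G [molecules / 100 eV] / 100
  per_g <- vapply(c("alpha", "beta", "gamma"), function(r)
    sum(unclass(acts) * E[[r]]) * 1e6 * G[[r]] / 100, numeric(1))
  solid <- rho * (1 - phi)                              # g solid per cm3 sediment
  molecules <- sum(per_g) * solid
  mol <- molecules / radh2_constants$NA_mol
  structure(list(
    molecules_cm3_yr = molecules,
    mol_cm3_yr       = mol,
    eeq_mol_cm3_yr   = to_electron_equivalents(mol, "H2"),
    by_radiation     = per_g * rho
  ), class = "production_rate")
}

#' Stoichiometric oxidant production
#'
#' Water radiolysis produces H2 and oxidants in stoichiometric balance
#' (2H2O -> H2 + H2O2), so the oxidant production rate in electron
#' equivalents equals the H2 production rate in electron equivalents,
#' exactly.
#'
#' @param p a `production_rate`, or a numeric H2 rate already in
#'   mol e-eq cm-3 yr-1.
#' @return oxidant production, mol e-eq cm-3 yr-1.
#' @export
oxidant_production <- function(p) {
  if (inherits(p, "production_rate")) return(p$eeq_mol_cm3_yr)
  as.numeric(p)
}

#' Sensitivity of total production to the beta-yield assumption
#'
#' The default model sets G(beta) = G(gamma) for the same medium. This
#' routine recomputes the total production with the alternatives
#' G(beta) = G(gamma, pure water) and G(beta) = G(alpha, same medium), and
#' reports the relative difference of each alternative from the default,
#' together with beta's fraction of total production and of total deposited
#' decay energy under the default assumption.
#'
#' @inheritParams production_rate
#' @return list: `beta_fraction` (of production, default assumption),
#'   `beta_energy_fraction` (of deposited decay energy),
#'   `sensitivity` named vector (`pure_water`, `alpha`), relative.
#' @export
beta_assumption_sensitivity <- function(acts, rho, phi, medium,
                                        energies = energy_partition(),
                                        yields = yield_table()) {
  base <- production_rate(acts, rho, phi, medium, energies, yields)
  total <- function(p) sum(p$by_radiation)
  t0 <- total(base)
  alts <- c(pure_water = yield_lookup(yields, "pure_water", "gamma"),
            alpha      = yield_lookup(yields, medium, "alpha"))
  sens <- vapply(alts, function(g) {
    alt <- production_rate(acts, rho, phi, medium, energies, yields, beta_G = g)
    abs(total(alt) - t0) / t0
  }, numeric(1))
  E <- energies[names(acts), ]
  e_by_rad <- vapply(c("alpha", "beta", "gamma"),
                     function(r) sum(unclass(acts) * E[[r]]), numeric(1))
  list(beta_fraction        = base$by_radiation[["beta"]] / t0,
       beta_energy_fraction = e_by_rad[["beta"]] / sum(e_by_rad),
       sensitivity          = sens)
}

#' Convert a molar volumetric concentration to nanomolar
#'
#' mol cm-3 (porewater) -> nmol L-1.
#' @param x mol cm-3.
#' @export
mol_cm3_to_nM <- function(x) x * 1e12
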