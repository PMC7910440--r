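# Global rollup: assign lithology-specific parameters over a lat/lon grid,
# apply the regional reclassification rules, depth-integrate each cell and
# sum to a global radiolytic production rate.

#' Packaged lithology parameter table
#'
#' Lithology-typical U, Th, K2O content, grain density and seafloor porosity
#' for the five seafloor categories. Values are literature-typical defaults
#' (provenance column) and overridable via `path`.
#'
#' @param path optional replacement CSV of the same shape.
#' @export
lithology_parameters <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.radH2$lith)) {
      .radH2$lith <- utils::read.csv(.extdata("lithology_parameters.csv"),
                                     stringsAsFactors = FALSE)
    }
    return(.radH2$lith)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Construct a seafloor grid
#'
#' @param cells data.frame with columns lat, lon (cell centers, degrees),
#'   lithology (five categories or "unclassified"), thickness_m, phi0,
#'   water_depth_m, and optionally basin (e.g. "atlantic", used by the
#'   Atlantic reclassification rule).
#' @param resolution_deg cell size, degrees (default 5/60, i.e. 5 arc-min).
#' @return object of class `seafloor_grid`.
#' @export
seafloor_grid <- function(cells, resolution_deg = 5 / 60) {
  need <- c("lat", "lon", "lithology", "thickness_m", "phi0", "water_depth_m")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("grid missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(abs(cells$lat) <= 90), all(cells$thickness_m >= 0))
  cl <- cells$lithology != "unclassified"
  stopifnot(all(cells$phi0[cl] > 0 & cells$phi0[cl] < 1))
  if (!"basin" %in% names(cells)) cells$basin <- NA_character_
  structure(list(cells = cells, resolution_deg = resolution_deg),
            class = "seafloor_grid")
}

#' Apply regional reclassification rules and lithology parameters
#'
#' Rules, applied in order: (i) cells in the Southern Ocean opal belt
#' (57-66 deg S) become siliceous ooze; (ii) latitude bands 50-57 deg S,
#' 66-90 deg S, and the Arctic (>= 70 deg N) become lithogenous;
#' (iii) Atlantic cells classified as abyssal clay take the parameters of
#' calcareous marl (sediment at depth in the Atlantic is carbonate-bearing
#' even where the seafloor is clay). Each cell then carries its category's
#' U/Th/K, grain density and G-value set; lithology is constant with depth.
#' Unclassified cells are excluded from the sum and counted in the coverage
#' diagnostics.
#'
#' @param grid a [seafloor_grid()].
#' @param params lithology parameter table, see [lithology_parameters()].
#' @param reclassify apply the regional rules (default TRUE).
#' @return the grid with an added `param_lithology` column and parameter
#'   columns merged into `cells`.
#' @export
assign_parameters <- function(grid, params = lithology_parameters(),
                              reclassify = TRUE) {
  stopifnot(inherits(grid, "seafloor_grid"))
  cells <- grid$cells
  lith <- cells$lithology
  if (reclassify) {
    lith[cells$lat >= -66 & cells$lat <= -57] <- "siliceous_ooze"
    lith[(cells$lat >= -57 & cells$lat <= -50) | cells$lat < -66 |
           cells$lat >= 70] <- "lithogenous"
    atl <- !is.na(cells$basin) & cells$basin == "atlantic" & lith == "abyssal_clay"
    lith[atl] <- "calcareous_marl"
  }
  cells$param_lithology <- lith
  idx <- match(lith, params$lithology)
  for (v in c("U_ppm", "Th_ppm", "K2O_wt_pct", "grain_density_g_cm3"))
    cells[[v]] <- params[[v]][idx]
  grid$cells <- cells
  grid$parameterized <- TRUE
  grid
}

#' Spherical cell area
#'
#' Area of a lat/lon quadrilateral of width `resolution_deg` centered at
#' `lat` on a sphere of authalic Earth radius:
#' R^2 dlambda (sin(lat + d/2) - sin(lat - d/2)).
#'
#' @param lat cell-center latitude, degrees; vectorized.
#' @param resolution_deg cell size, degrees.
#' @return area, km2.
#' @export
cell_area_km2 <- function(lat, resolution_deg) {
  stopifnot(all(abs(lat) <= 90))
  rad <- pi / 180
  half <- resolution_deg / 2
  radh2_constants$R_earth_km^2 * (resolution_deg * rad) *
    (sin(pmin(lat + half, 90) * rad) - sin(pmax(lat - half, -90) * rad))
}

#' Global radiolytic production from a parameterized grid
#'
#' Depth-integrates every classified cell with [integrate_column()] (1-m
#' steps, 0.1%-porosity halt) and forms the area-weighted global sum. Cells
#' with zero sediment thickness contribute zero; unclassified cells are
#' excluded and reported in the coverage diagnostics. Because H2 and oxidant
#' production are stoichiometrically balanced, the oxidant total equals the
#' H2 total in electron equivalents; the combined total is their sum.
#'
#' @param grid a parameterized [seafloor_grid()] (see [assign_parameters()]).
#' @param energies,yields constant tables.
#' @param dz_m integration step, m.
#' @return list of class `global_result`: `cells` (with
#'   `areal_eeq_mol_cm2_yr` and `area_km2`), totals `total_H2_eeq_mol_yr`,
#'   `total_oxidant_eeq_mol_yr`, `total_combined_eeq_mol_yr`, and `coverage`
#'   (classified area fraction).
#' @export
global_production <- function(grid, energies = energy_partition(),
                              yields = yield_table(), dz_m = 1) {
  stopifnot(inherits(grid, "seafloor_grid"))
  if (!isTRUE(grid$parameterized)) stop("run assign_parameters() first")
  cells <- grid$cells
  classified <- cells$param_lithology %in% lithology_parameters()$lithology
  if (!any(classified)) stop("all grid cells are unclassified")
  cells$area_km2 <- cell_area_km2(cells$lat, grid$resolution_deg)
  areal <- numeric(nrow(cells))
  # identical parameter tuples share one column integration
  key <- paste(cells$param_lithology, cells$thickness_m, cells$phi0,
               compaction_coefficient(cells$water_depth_m))
  idx <- which(classified & cells$thickness_m > 0)
  for (g in split(idx, key[idx])) {
    i <- g[1]
    col <- sediment_column(
      lithology = cells$param_lithology[i], thickness_m = cells$thickness_m[i],
      water_depth_m = cells$water_depth_m[i], phi0 = cells$phi0[i],
      rho = cells$grain_density_g_cm3[i],
      composition = elemental_composition(cells$U_ppm[i], cells$Th_ppm[i],
                                          K2O_wt_pct = cells$K2O_wt_pct[i]))
    areal[g] <- integrate_column(col, energies, yields, dz_m)$areal_eeq_mol_cm2_yr
  }
  cells$areal_eeq_mol_cm2_yr <- ifelse(classified, areal, NA_real_)
  cm2_per_km2 <- 1e10
  total <- sum(cells$areal_eeq_mol_cm2_yr[classified] *
                 cells$area_km2[classified]) * cm2_per_km2
  structure(list(
    cells = cells,
    total_H2_eeq_mol_yr = total,
    total_oxidant_eeq_mol_yr = total,
    total_combined_eeq_mol_yr = 2 * total,
    coverage = sum(cells$area_km2[classified]) / sum(cells$area_km2)
  ), class = "global_result")
}
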