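# Seeded synthetic inputs with the statistical structure the analysis
# assumes: lithology-typical columns, porewater profiles forward-modelled
# from known rate fields (so inversion tests can check recovery against the
# stored truth), and small lat/lon lithology mosaics with margin-correlated
# thickness. All draws flow from the seed passed to each generator; no
# global random state is relied on.

#' Generate a lithology-typical sediment column
#'
#' Thickness, seafloor porosity, grain density and U/Th/K content are drawn
#' from documented lithology-typical ranges (centered on the packaged
#' parameter table, with modest jitter). Abyssal clay draws phi0 in
#' [0.80, 0.85], the typical abyssal-clay range. Reproducible per seed.
#'
#' @param lithology one of the five seafloor categories.
#' @param seed integer seed.
#' @return a [sediment_column()].
#' @export
synth_column <- function(lithology, seed = 1) {
  params <- lithology_parameters()
  row <- params[params$lithology == lithology, ]
  if (nrow(row) == 0) stop("unknown lithology: ", lithology)
  set.seed(seed)
  phi0 <- if (lithology == "abyssal_clay") stats::runif(1, 0.80, 0.85)
          else min(max(stats::rnorm(1, row$phi0_default, 0.02), 0.3), 0.95)
  water_depth <- switch(lithology,
    abyssal_clay = stats::runif(1, 4000, 6000),
    calcareous_ooze = stats::runif(1, 3000, 4500),
    siliceous_ooze = stats::runif(1, 3500, 5000),
    calcareous_marl = stats::runif(1, 2500, 4500),
    lithogenous = stats::runif(1, 100, 2500))
  # open-ocean columns thin, margins thick
  thickness <- if (lithology %in% c("abyssal_clay", "calcareous_ooze",
                                    "siliceous_ooze"))
    stats::runif(1, 20, 130) else 10^stats::runif(1, 2, 3.5)
  jit <- function(x) x * exp(stats::rnorm(1, 0, 0.15))
  comp <- elemental_composition(jit(row$U_ppm), jit(row$Th_ppm),
                                K2O_wt_pct = jit(row$K2O_wt_pct))
  sediment_column(lithology, thickness, water_depth, phi0,
                  row$grain_density_g_cm3, comp,
                  basement_age_Ma = stats::runif(1, 10, 120))
}

#' Forward-model a porewater profile from a known rate field
#'
#' Solves the steady-state diffusion equation with the prescribed net rate
#' field (per bulk-sediment volume; negative = consumption) on a fine grid,
#' samples it at `n_depths` evenly spaced depths, and adds i.i.d. Gaussian
#' measurement noise. The noise-free truth (rate field, depth-integrated
#' rate, exact concentrations) is stored in attributes for recovery tests.
#'
#' @param rate_fun function of depth (m) returning the net rate,
#'   mol cm-3 sediment yr-1.
#' @param Z_m profile length, m.
#' @param phi,FF,D_cm2_yr transport parameters (FF defaults to phi^-2).
#' @param top_uM,bottom_uM boundary concentrations, micromolar.
#' @param n_depths number of sampled depths.
#' @param noise_sd_uM Gaussian measurement sd, micromolar.
#' @param seed integer seed.
#' @return data.frame depth_m, conc_uM, sigma_uM with attributes
#'   `truth_rate_fun`, `truth_integrated_mol_cm2_yr`, `conc_true_uM`, `phi`,
#'   `FF`, `D_cm2_yr`.
#' @export
synth_porewater_profile <- function(rate_fun, Z_m, phi, FF = NULL, D_cm2_yr,
                                    top_uM = 200, bottom_uM = 100,
                                    n_depths = 40, noise_sd_uM = 1,
                                    seed = 1) {
  if (is.null(FF)) FF <- phi^(-2)
  layers <- data.frame(thickness_m = Z_m, P_pw = 0,
                       phi = phi, FF = FF, D = D_cm2_yr)
  # net rate per sediment volume -> source per porewater volume, in uM/yr
  sol <- numeric_profile(layers, n_nodes = 4001,
                         top_bc = top_uM, bottom_bc = bottom_uM,
                         P_fun = function(z) rate_fun(z) / phi * 1e9)
  depth <- seq(0, Z_m, length.out = n_depths)
  conc_true <- stats::approx(sol$x_m, sol$conc, xout = depth)$y
  if (any(conc_true < 0))
    warning("forward-modelled concentrations go negative; ",
            "check rate field and boundary conditions")
  set.seed(seed)
  conc <- pmax(conc_true + stats::rnorm(n_depths, 0, noise_sd_uM), 0)
  out <- data.frame(depth_m = depth, conc_uM = conc, sigma_uM = noise_sd_uM)
  z_cm <- 100 * Z_m
  attr(out, "truth_rate_fun") <- rate_fun
  attr(out, "truth_integrated_mol_cm2_yr") <-
    stats::integrate(function(z) rate_fun(z), 0, Z_m)$value * 100
  attr(out, "conc_true_uM") <- conc_true
  attr(out, "phi") <- phi; attr(out, "FF") <- FF
  attr(out, "D_cm2_yr") <- D_cm2_yr
  out
}

#' Generate a synthetic seafloor grid
#'
#' Builds an n_lat x n_lon mosaic in which margin cells (near the synthetic
#' "continents") are shallow, lithogenous and carry thick sediment, while
#' open-ocean cells are deep, clay/ooze-dominated and thinly covered;
#' thickness spans >= 4 orders of magnitude across the grid. If `mix` is
#' supplied, lithologies are instead drawn i.i.d. from that categorical
#' distribution. Reproducible per seed.
#'
#' @param n_lat,n_lon grid shape.
#' @param seed integer seed.
#' @param mix optional named probability vector over lithology categories.
#' @return a [seafloor_grid()].
#' @export
synth_grid <- function(n_lat = 18, n_lon = 36, seed = 1, mix = NULL) {
  set.seed(seed)
  res_lat <- 180 / n_lat; res_lon <- 360 / n_lon
  lat <- seq(-90 + res_lat / 2, 90 - res_lat / 2, by = res_lat)
  lon <- seq(-180 + res_lon / 2, 180 - res_lon / 2, by = res_lon)
  cells <- expand.grid(lon = lon, lat = lat)
  n <- nrow(cells)
  # synthetic continents at lon = -180/0/180; margin proximity in [0, 1]
  margin <- 1 - pmin(abs(cells$lon %% 180), 180 - abs(cells$lon %% 180)) / 90
  margin <- pmin(pmax(margin + stats::rnorm(n, 0, 0.08), 0), 1)
  cells$water_depth_m <- pmax(100, 5600 * (1 - margin^2) + stats::rnorm(n, 0, 300))
  # thin pelagic drapes (metres, young/starved crust) to multi-km margin
  # wedges: >= 4 orders of magnitude of thickness across a global mosaic
  cells$thickness_m <- pmin(pmax(10^(4.3 * margin + stats::rnorm(n, 0, 0.35)),
                                 0.5), 18000)
  if (is.null(mix)) {
    lith <- ifelse(margin > 0.6, "lithogenous",
            ifelse(cells$water_depth_m > 4600, "abyssal_clay",
            ifelse(abs(cells$lat) < 10, "siliceous_ooze",
            ifelse(cells$water_depth_m > 3800, "calcareous_marl",
                   "calcareous_ooze"))))
  } else {
    lith <- sample(names(mix), n, replace = TRUE, prob = mix)
  }
  params <- lithology_parameters()
  cells$lithology <- lith
  phi_tab <- stats::setNames(params$phi0_default, params$lithology)
  cells$phi0 <- pmin(pmax(phi_tab[lith] + stats::rnorm(n, 0, 0.02), 0.35), 0.9)
  cells$basin <- ifelse(cells$lon >= -70 & cells$lon < 20, "atlantic", "pacific")
  seafloor_grid(cells, resolution_deg = res_lat)
}
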