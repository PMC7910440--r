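# Gibbs-energy evaluation of the Knallgas reaction (H2 + 1/2 O2 -> H2O) and
# the ratio analysis of radiolytic electron supply versus organic-fuelled
# respiration as a function of sediment age.

#' In situ Gibbs energy of reaction
#'
#' dG_r = dG0_r(T,P) + 2.3 R T log10(Q), in kJ per mol H2, with
#' R = 8.314e-3 kJ mol-1 K-1.
#'
#' @param dG0_r standard-state Gibbs energy at in situ T and P, kJ (mol H2)-1.
#' @param T_K temperature, K.
#' @param Q activity quotient (> 0).
#' @export
gibbs_energy <- function(dG0_r, T_K, Q) {
  stopifnot(T_K > 0)
  if (any(Q <= 0)) stop("Q must be > 0")
  dG0_r + 2.3 * radh2_constants$R_kJ * T_K * log10(Q)
}

#' Standard-state Gibbs energy of the Knallgas reaction
#'
#' Default linear temperature model for H2(aq) + 1/2 O2(aq) -> H2O(l) on the
#' aqueous-species basis (consistent with using dissolved activities in Q):
#' dG0(T) = dH0 - T dS0 with dH0 = -275.8 kJ mol-1, dS0 = -43.2 J mol-1 K-1
#' (about -263 kJ mol-1 at 298 K). Pressure dependence is small for this
#' reaction over seafloor pressures and is not modelled; supplying
#' site-specific values is encouraged.
#'
#' @param T_K temperature, K.
#' @export
dG0_knallgas <- function(T_K) -275.8 + T_K * 0.0432

#' Activity quotient of the Knallgas reaction
#'
#' Q = a_H2O / (a_H2 * a_O2^(1/2)), with unit water activity by default.
#' Activity coefficients default to 1 (activities = molal concentrations)
#' when not supplied upstream.
#'
#' @param a_H2,a_O2 dissolved activities (> 0).
#' @param a_H2O water activity (default 1).
#' @export
knallgas_quotient <- function(a_H2, a_O2, a_H2O = 1) {
  if (any(c(a_H2, a_O2, a_H2O) <= 0)) stop("activities must be > 0")
  a_H2O / (a_H2 * sqrt(a_O2))
}

#' Ratio of radiolytic production to net organic-fuelled respiration vs age
#'
#' Converts both sides to electron equivalents (the organic rate via the
#' species factor: 4 e- per O2 reduced or per organic C oxidized to DIC) and
#' forms, per depth interval of the net-rate profile, the ratio of magnitudes
#' radiolytic e-eq production / net organic e-eq rate, placed at the age of
#' the interval midpoint. Because oxidants are produced stoichiometrically
#' with H2, the oxidant-based ratio equals the H2-based ratio in electron
#' equivalents by construction. Rate uncertainty is propagated to the ratio
#' (sd_ratio = ratio * sd_rate/|rate|). Intervals with zero organic rate are
#' flagged infinite and excluded from summary statistics.
#'
#' @param radiolytic_eeq radiolytic production, mol e-eq cm-3 sediment yr-1:
#'   a scalar or a function of depth (m).
#' @param net_rates a `net_rate_profile` (rates in mol of species cm-3 yr-1).
#' @param species species of the inverted profile: "O2" or "organic_C" (DIC).
#' @param col a [sediment_column()] with a basement age, for depth-to-age.
#' @return data.frame of class `ratio_series`: age_Ma, ratio, sd, z_mid_m.
#' @export
ratio_series <- function(radiolytic_eeq, net_rates, species, col) {
  stopifnot(inherits(net_rates, "net_rate_profile"))
  species <- match.arg(species, c("O2", "organic_C"))
  iv <- net_rates$intervals
  z_mid <- (iv$z_top_m + iv$z_bot_m) / 2
  rad <- .field_fun(radiolytic_eeq)(z_mid)
  org_eeq <- abs(to_electron_equivalents(iv$rate_mol_cm3_yr, species))
  ratio <- ifelse(org_eeq > 0, rad / org_eeq, Inf)
  sd <- rep(NA_real_, nrow(iv))
  if ("sd_mol_cm3_yr" %in% names(iv)) {
    rel <- ifelse(abs(iv$rate_mol_cm3_yr) > 0,
                  iv$sd_mol_cm3_yr / abs(iv$rate_mol_cm3_yr), NA_real_)
    sd <- ifelse(is.finite(ratio), ratio * rel, NA_real_)
  }
  out <- data.frame(age_Ma = depth_to_age(z_mid, col), ratio = ratio,
                    sd = sd, z_mid_m = z_mid)
  out <- out[order(out$age_Ma), ]
  class(out) <- c("ratio_series", class(out))
  out
}

#' Age at which the radiolytic/organic ratio first reaches 1
#'
#' Smallest age with ratio >= 1, linearly interpolated between the bracketing
#' points; NA if the ratio never reaches 1. Non-finite ratios are excluded.
#'
#' @param series a [ratio_series()] (needs columns age_Ma, ratio).
#' @return age, Ma, or NA.
#' @export
crossover_age <- function(series) {
  s <- series[is.finite(series$ratio), , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  s <- s[order(s$age_Ma), ]
  if (s$ratio[1] >= 1) return(s$age_Ma[1])
  above <- which(s$ratio >= 1)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  a0 <- s$age_Ma[i - 1]; a1 <- s$age_Ma[i]
  r0 <- s$ratio[i - 1];  r1 <- s$ratio[i]
  a0 + (1 - r0) / (r1 - r0) * (a1 - a0)
}
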