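# Shared fixtures: a typical abyssal-clay composition/column and a smooth
# organic consumption field used by the inversion tests.

clay_comp <- function() elemental_composition(2.6, 13.4, K2O_wt_pct = 3.0)

clay_column <- function(thickness_m = 70, basement_age_Ma = 100) {
  sediment_column("abyssal_clay", thickness_m, water_depth_m = 5000,
                  phi0 = 0.83, rho = 2.60, composition = clay_comp(),
                  basement_age_Ma = basement_age_Ma)
}

# exponential-decay net consumption (mol cm-3 sediment yr-1, negative)
expdecay_rate <- function(R0 = 5e-12, zstar = 15) {
  function(z) -R0 * exp(-z / zstar)
}

# average of a rate function over the intervals of a net_rate_profile
interval_truth <- function(rate_fun, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    stats::integrate(rate_fun, intervals$z_top_m[i], intervals$z_bot_m[i])$value /
      (intervals$z_bot_m[i] - intervals$z_top_m[i])
  }, numeric(1))
}
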