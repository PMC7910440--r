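# Steady-state dissolved-H2 diffusion profiles expected from radiolytic
# production in the absence of consumption.
#
# Governing balance (porewater concentration C, depth x):
#   dC/dt = (D/(phi F)) d2C/dx2 + P,   P per porewater volume
# At steady state with constant P: d2C/dx2 = -P phi F / D, and with
# zero-concentration boundaries at the seafloor (x = 0, diffusive loss to
# bottom water) and basement (x = Z, diffusive loss to basement):
#   C(x) = 1/2 (P phi F / D) (x Z - x^2)
# All solver internals work in cm; depths are accepted in m at the interface.

#' Transport parameter set
#'
#' @param D_cm2_yr free-solution diffusion coefficient of H2 at in situ
#'   temperature, cm2 yr-1.
#' @param phi porosity fraction in (0, 1).
#' @param FF formation factor (>= 1); defaults to the Archie-type
#'   F = phi^-2 when not measured.
#' @param Z_m sediment column thickness, m.
#' @return object of class `transport_params`.
#' @export
transport_params <- function(D_cm2_yr, phi, FF = NULL, Z_m) {
  if (is.null(FF)) FF <- phi^(-2)
  stopifnot(D_cm2_yr > 0, phi > 0, phi < 1, FF >= 1, Z_m > 0)
  structure(list(D = D_cm2_yr, phi = phi, FF = FF, Z_cm = Z_m * 100),
            class = "transport_params")
}

#' Diffusion coefficient of dissolved H2 in seawater
#'
#' Empirical linear temperature fit for the free-solution diffusivity of
#' H2(aq), D ~ (25.9 + 0.81 T[degC]) x 1e-6 cm2 s-1, returned in cm2 yr-1.
#' Supply a measured value to the solvers to override.
#'
#' @param T_C in situ temperature, degrees C.
#' @export
D_H2 <- function(T_C) (25.9 + 0.81 * T_C) * 1e-6 * radh2_constants$sec_per_yr

#' Closed-form steady-state H2 profile (uniform column)
#'
#' @param P_pw production rate per porewater volume-time (e.g.
#'   mol cm-3 porewater yr-1; the output concentration carries the same
#'   amount unit per cm3).
#' @param params a [transport_params()].
#' @param x_m depth(s) below seafloor, m; must lie in [0, Z].
#' @return concentration at `x_m` (amount per cm3 porewater).
#' @export
steady_state_profile <- function(P_pw, params, x_m) {
  stopifnot(inherits(params, "transport_params"))
  x <- x_m * 100
  if (any(x < 0 | x > params$Z_cm + 1e-9)) stop("x_m outside [0, Z]")
  0.5 * (P_pw * params$phi * params$FF / params$D) * (x * params$Z_cm - x^2)
}

.layers_check <- function(layers) {
  need <- c("thickness_m", "P_pw", "phi", "FF", "D")
  miss <- setdiff(need, names(layers))
  if (length(miss)) stop("layers missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(layers$thickness_m > 0), all(layers$phi > 0 & layers$phi < 1),
            all(layers$FF >= 1), all(layers$D > 0))
  layers
}

#' Finite-difference steady-state profile for a layered column
#'
#' Second-order conservative discretization of
#' d/dx(k dC/dx) = -P(x), k = D/(phi F), with Dirichlet boundaries
#' (zero by default) and harmonic-mean face diffusivities, which enforces
#' continuity of the diffusive flux -k dC/dx at internal layer interfaces.
#'
#' @param layers data.frame with columns thickness_m, P_pw, phi, FF, D
#'   (one row per layer, top to bottom; units as in
#'   [steady_state_profile()]).
#' @param n_nodes number of grid nodes (>= 3).
#' @param top_bc,bottom_bc boundary concentrations (default 0).
#' @param P_fun optional smooth source function of depth (m), per porewater
#'   volume, overriding the per-layer constant `P_pw`.
#' @return data.frame `x_m`, `conc` of class `H2_profile` (flag "expected").
#' @export
numeric_profile <- function(layers, n_nodes = 2001, top_bc = 0, bottom_bc = 0,
                            P_fun = NULL) {
  layers <- .layers_check(layers)
  if (n_nodes < 3) stop("n_nodes must be >= 3")
  Z <- sum(layers$thickness_m) * 100
  x <- seq(0, Z, length.out = n_nodes)
  h <- x[2] - x[1]
  tops <- cumsum(c(0, layers$thickness_m * 100))
  layer_of <- function(xx) pmin(findInterval(xx, tops, rightmost.closed = TRUE),
                                nrow(layers))
  # coefficients sampled at cell-face midpoints: the flux -k dC/dx is then
  # evaluated with the correct layer's k on each side of an interface, and
  # the nodal source is the mean of the two adjacent face values (exact for
  # piecewise-parabolic solutions when an interface falls on a node)
  x_face <- (x[-n_nodes] + x[-1]) / 2
  lf <- layer_of(x_face)
  kf <- (layers$D / (layers$phi * layers$FF))[lf]
  if (is.null(P_fun)) {
    P_face <- layers$P_pw[lf]
    P_node <- c(0, (P_face[-(n_nodes - 1)] + P_face[-1]) / 2, 0)
  } else {
    P_node <- P_fun(x / 100)
  }
  m <- n_nodes - 2
  lower <- kf[1:m]; upper <- kf[2:(m + 1)]
  diag_ <- -(lower + upper)
  rhs <- -P_node[2:(n_nodes - 1)] * h^2
  rhs[1] <- rhs[1] - lower[1] * top_bc
  rhs[m] <- rhs[m] - upper[m] * bottom_bc
  # Thomas algorithm
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- upper[1] / diag_[1]; dp[1] <- rhs[1] / diag_[1]
  if (m > 1) for (i in 2:m) {
    den <- diag_[i] - lower[i] * cp[i - 1]
    if (abs(den) < .Machine$double.eps) stop("singular system in numeric_profile")
    cp[i] <- upper[i] / den
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / den
  }
  C <- numeric(m); C[m] <- dp[m]
  if (m > 1) for (i in (m - 1):1) C[i] <- dp[i] - cp[i] * C[i + 1]
  out <- data.frame(x_m = x / 100, conc = c(top_bc, C, bottom_bc))
  attr(out, "flag") <- "expected"
  class(out) <- c("H2_profile", class(out))
  out
}

#' Closed-form two-layer steady-state profile
#'
#' Piecewise-parabolic solution with zero concentration at the top and
#' bottom boundaries and, at the internal interface, continuity of
#' concentration and of the diffusive flux -(D/(phi F)) dC/dx.
#' With identical layers it reduces pointwise to the single-layer
#' closed form.
#'
#' @param layers data.frame with exactly 2 rows (see [numeric_profile()]).
#' @param x_m depths at which to evaluate, m.
#' @return concentration at `x_m`.
#' @export
two_layer_profile <- function(layers, x_m) {
  layers <- .layers_check(layers)
  if (nrow(layers) != 2) stop("two_layer_profile needs exactly 2 layers")
  a <- layers$thickness_m[1] * 100
  Z <- sum(layers$thickness_m) * 100
  k <- layers$D / (layers$phi * layers$FF)
  q <- layers$P_pw / k                                   # -C'' per layer
  # unknowns A1, A2:  C1 = -q1 x^2/2 + A1 x ;  C2 = -q2 x^2/2 + A2 x + B2
  # C2(Z) = 0  =>  B2 = q2 Z^2/2 - A2 Z
  # flux:  k1 (A1 - q1 a) = k2 (A2 - q2 a)
  # conc:  A1 a - A2 a + (q2 - q1) a^2/2 - q2 Z^2/2 + A2 Z = 0
  M <- rbind(c(k[1], -k[2]),
             c(a,    Z - a))
  v <- c(a * (k[1] * q[1] - k[2] * q[2]),
         q[2] * Z^2 / 2 - (q[2] - q[1]) * a^2 / 2)
  A <- solve(M, v)
  B2 <- q[2] * Z^2 / 2 - A[2] * Z
  x <- x_m * 100
  if (any(x < 0 | x > Z + 1e-9)) stop("x_m outside [0, Z]")
  ifelse(x <= a,
         -q[1] * x^2 / 2 + A[1] * x,
         -q[2] * x^2 / 2 + A[2] * x + B2)
}

#' Compare measured and expected H2 profiles
#'
#' Interpolates the expected profile onto the measured depths and reports the
#' per-depth ratio expected/measured. Measurements below the detection limit
#' are replaced by the detection limit and flagged: their ratios are lower
#' bounds. Consumption is flagged when the median ratio exceeds 10.
#'
#' @param measured data.frame with depth_m, H2_nM and optionally
#'   detection_limit_nM.
#' @param expected data.frame with x_m (or depth_m) and conc (nM).
#' @return list: `table` (depth_m, measured_nM, expected_nM, ratio,
#'   censored), `median_ratio`, `orders_of_magnitude` (log10 of median
#'   ratio), `consumption_flag`.
#' @export
compare_profiles <- function(measured, expected) {
  xm <- if ("x_m" %in% names(expected)) expected$x_m else expected$depth_m
  common <- measured$depth_m >= min(xm) & measured$depth_m <= max(xm)
  if (!any(common)) stop("no common depth support between profiles")
  m <- measured[common, , drop = FALSE]
  exp_at <- stats::approx(xm, expected$conc, xout = m$depth_m)$y
  dl <- if ("detection_limit_nM" %in% names(m)) m$detection_limit_nM else 0
  censored <- m$H2_nM < dl
  meas_eff <- pmax(m$H2_nM, dl)
  ratio <- exp_at / meas_eff
  med <- stats::median(ratio, na.rm = TRUE)
  list(table = data.frame(depth_m = m$depth_m, measured_nM = m$H2_nM,
                          expected_nM = exp_at, ratio = ratio,
                          censored = censored),
       median_ratio = med,
       orders_of_magnitude = log10(med),
       consumption_flag = is.finite(med) && med > 10)
}
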