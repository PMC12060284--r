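#' Seawater physical properties
#'
#' Ambient-water property correlations used by the bubble and transport
#' stages: density (EOS-80 surface polynomial), dynamic viscosity
#' (Sharqawy et al. 2010), air-water surface tension (IAPWS, with a salinity
#' correction), and absolute pressure at depth assuming a hydrostatic column.
#'
#' @param T temperature, degrees C.
#' @param S practical salinity, ppt.
#' @param depth depth below the surface, m (positive down).
#' @param rho water density used for the hydrostatic term, kg/m3.
#'
#' @return `sw_density` kg/m3; `sw_viscosity` Pa s; `sw_surface_tension` N/m;
#'   `pressure_at_depth` Pa (absolute, including one standard atmosphere).
#' @name seawater
NULL

.check_TS <- function(T, S) {
  if (any(!is.finite(T)) || any(T < -2) || any(T > 40))
    stop("temperature out of range [-2, 40] degC", call. = FALSE)
  if (any(!is.finite(S)) || any(S < 0) || any(S > 42))
    stop("salinity out of range [0, 42] ppt", call. = FALSE)
  invisible(TRUE)
}

#' @rdname seawater
#' @export
sw_density <- function(T, S) {
  .check_TS(T, S)
  # EOS-80 one-atmosphere International Equation of State of Seawater
  rho_w <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
    8.2467e-7 * T^3 + 5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2
}

#' @rdname seawater
#' @export
sw_viscosity <- function(T, S) {
  .check_TS(T, S)
  mu_w <- 4.2844e-5 + 1 / (0.157 * (T + 64.993)^2 - 91.296)
  s <- S / 1000  # kg/kg
  A <- 1.541 + 1.998e-2 * T - 9.52e-5 * T^2
  B <- 7.974 - 7.561e-2 * T + 4.724e-4 * T^2
  mu_w * (1 + A * s + B * s^2)
}

#' @rdname seawater
#' @export
sw_surface_tension <- function(T, S) {
  .check_TS(T, S)
  TK <- T + 273.15
  tau <- 1 - TK / 647.096
  sigma_w <- 0.2358 * tau^1.256 * (1 - 0.625 * tau)
  sigma_w * (1 + (0.000226 * T + 0.00946) * log(1 + 0.0331 * S))
}

#' @rdname seawater
#' @export
pressure_at_depth <- function(depth, rho = 1027) {
  if (any(depth < 0)) stop("depth must be non-negative", call. = FALSE)
  101325 + rho * 9.81 * depth
}
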