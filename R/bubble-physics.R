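#' Ambient fluid properties bundle
#'
#' Convenience constructor collecting the seawater properties the bubble
#' correlations need at one (T, S) condition.
#'
#' @inheritParams seawater
#' @param rho_gas gas density inside the bubble, kg/m3 (affects buoyancy
#'   only weakly; defaults to 0 so the buoyancy term uses the full water
#'   density contrast when the caller has no composition at hand).
#' @return list with `rho` (kg/m3), `mu` (Pa s), `sigma` (N/m), `drho`.
#' @export
fluid_properties <- function(T, S, rho_gas = 0) {
  rho <- sw_density(T, S)
  list(rho = rho, mu = sw_viscosity(T, S), sigma = sw_surface_tension(T, S),
       drho = rho - rho_gas)
}

# Eotvos number, Morton number and the Clift/Grace H parameter
.bubble_numbers <- function(d, fp) {
  g <- 9.81
  Eo <- g * fp$drho * d^2 / fp$sigma
  Mo <- g * fp$mu^4 * fp$drho / (fp$rho^2 * fp$sigma^3)
  H <- 4 / 3 * Eo * Mo^(-0.149) * (fp$mu / 9e-4)^(-0.14)
  list(Eo = Eo, Mo = Mo, H = H)
}

#' Bubble shape regime
#'
#' Classifies a bubble as spherical, ellipsoidal or spherical-cap from the
#' Eotvos and Morton numbers via the Clift/Grace shape diagram (H-number
#' thresholds). Small bubbles are spherical, intermediate sizes in seawater
#' are ellipsoidal wobblers, and large caps appear beyond Eo = 40.
#'
#' @param d equivalent spherical diameter, m.
#' @param fp fluid properties from [fluid_properties()].
#' @return one of `"spherical"`, `"ellipsoidal"`, `"spherical-cap"`.
#' @export
shape_regime <- function(d, fp) {
  if (d <= 0) stop("diameter must be positive", call. = FALSE)
  nb <- .bubble_numbers(d, fp)
  if (nb$Eo >= 40) return("spherical-cap")
  if (nb$H < 2) return("spherical")
  "ellipsoidal"
}

# clean-sphere drag of Mei, Klausner & Lawrence (1994); Cd -> 16/Re as Re -> 0
.us_sphere_clean <- function(d, fp) {
  g <- 9.81
  u <- g * fp$drho * d^2 / (12 * fp$mu)  # Hadamard-Rybczynski start
  for (i in 1:60) {
    Re <- pmax(fp$rho * u * d / fp$mu, 1e-12)
    Cd <- 16 / Re * (1 + (8 / Re + 0.5 * (1 + 3.315 * Re^(-0.5)))^(-1))
    u_new <- sqrt(4 * g * fp$drho * d / (3 * fp$rho * Cd))
    if (abs(u_new - u) < 1e-12 * (1 + u)) {
      u <- u_new
      break
    }
    u <- 0.5 * (u + u_new)
  }
  u
}

# Fan & Tsuchiya (1990) correlation, clean bubble / multicomponent liquid
.us_fan_tsuchiya <- function(d, fp) {
  g <- 9.81
  n <- 1.6   # clean interface
  c <- 1.4   # multicomponent (saline) liquid
  Mo <- .bubble_numbers(d, fp)$Mo
  Kb <- max(14.7 * Mo^(-0.038), 12)
  de_star <- d * sqrt(fp$rho * g / fp$sigma)
  u_star <- ((Mo^(-0.25) / Kb * de_star^2)^(-n) +
               (2 * c / de_star + de_star / 2)^(-n / 2))^(-1 / n)
  u_star * (fp$sigma * g / fp$rho)^0.25
}

.us_cap <- function(d, fp) {
  0.711 * sqrt(9.81 * d * fp$drho / fp$rho)  # Davies-Taylor
}

#' Terminal rise velocity of a clean bubble
#'
#' Clean-interface terminal velocity: Mei et al. drag law in the spherical
#' regime, Fan & Tsuchiya (1990) wave-analogy correlation (clean,
#' multicomponent-liquid parameters) in the ellipsoidal regime, and the
#' Davies-Taylor law for spherical caps. Branches are blended linearly in
#' the Clift H parameter over H in [1.5, 2.5] to avoid a jump at the
#' sphere/ellipsoid boundary.
#'
#' @inheritParams shape_regime
#' @param regime optional override of [shape_regime()].
#' @return rise velocity, m/s.
#' @export
rise_velocity <- function(d, fp, regime = NULL) {
  if (d <= 0) stop("diameter must be positive", call. = FALSE)
  if (is.null(regime)) regime <- shape_regime(d, fp)
  if (regime == "spherical-cap") return(.us_cap(d, fp))
  H <- .bubble_numbers(d, fp)$H
  if (H <= 1.5) return(.us_sphere_clean(d, fp))
  if (H >= 2.5) return(.us_fan_tsuchiya(d, fp))
  w <- (H - 1.5) / 1.0
  (1 - w) * .us_sphere_clean(d, fp) + w * .us_fan_tsuchiya(d, fp)
}

#' Bubble-water mass transfer coefficient
#'
#' Clean-bubble (mobile interface) transfer coefficient from the
#' potential-flow boundary-layer result Sh = 1.13 Pe^(1/2), applied per
#' component with its molecular diffusivity. Spherical caps exchange
#' somewhat faster per unit equivalent area; a factor 1.3 is applied there.
#'
#' @inheritParams shape_regime
#' @param u rise velocity, m/s.
#' @param D molecular diffusivity of the transferring component, m2/s
#'   (vectorized).
#' @param regime shape regime label.
#' @return transfer coefficient, m/s (same length as `D`).
#' @export
mass_transfer_coeff <- function(d, regime, u, D) {
  if (d <= 0) stop("diameter must be positive", call. = FALSE)
  if (u < 0 || any(D < 0)) stop("velocity and diffusivity must be non-negative", call. = FALSE)
  k <- 1.13 * sqrt(D * u / d)
  if (identical(regime, "spherical-cap")) k <- 1.3 * k
  k
}
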