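#' Gas component property table
#'
#' Physical constants for the three gases tracked by the bubble model:
#' methane (the seep gas) and the two dominant dissolved atmospheric gases,
#' nitrogen and oxygen, which flow into a rising bubble. Critical constants
#' and acentric factors feed the Peng-Robinson equation of state; Henry
#' constants (mol m-3 Pa-1 at 298.15 K, with van 't Hoff temperature
#' dependence and a per-ppt salting-out coefficient) feed the modified
#' Henry's law solubility; molecular diffusivities (m2/s at 25 C in fresh
#' water, rescaled by the Stokes-Einstein ratio T/mu) feed the bubble-water
#' mass transfer correlations.
#'
#' @param name one of `"CH4"`, `"N2"`, `"O2"` (or a vector of them).
#' @return `gas_component` returns a data frame with one row per component.
#' @export
gas_component <- function(name = c("CH4", "N2", "O2")) {
  name <- match.arg(name, several.ok = TRUE)
  tab <- data.frame(
    name     = c("CH4", "N2", "O2"),
    M        = c(16.043e-3, 28.014e-3, 31.999e-3),  # kg/mol
    Tc       = c(190.56, 126.20, 154.58),           # K
    Pc       = c(45.99e5, 33.98e5, 50.43e5),        # Pa
    omega    = c(0.011, 0.037, 0.022),              # acentric factor
    kh_ref   = c(1.4e-5, 6.4e-6, 1.2e-5),  # mol m-3 Pa-1 at 298.15 K
    dlnkh_dinvT = c(1900, 1600, 1700),     # K (van 't Hoff)
    k_salt   = c(0.0066, 0.0072, 0.0066),  # 1/ppt Setschenow-type
    D25      = c(1.85e-9, 2.00e-9, 2.30e-9),  # m2/s, fresh water, 25 C
    row.names = NULL
  )
  tab[match(name, tab$name), , drop = FALSE]
}

# atmospheric mole fractions of the dry atmosphere for the tracked gases
.atm_mole_fraction <- c(CH4 = 1.9e-6, N2 = 0.7808, O2 = 0.2095)

#' Molecular diffusivity of a dissolved gas in seawater
#'
#' Reference 25 C fresh-water diffusivities rescaled by the Stokes-Einstein
#' ratio `T_K / mu(T, S)` so that colder, more viscous water gives slower
#' molecular diffusion.
#'
#' @inheritParams gas_component
#' @inheritParams seawater
#' @return diffusivity, m2/s.
#' @export
molecular_diffusivity <- function(name, T, S) {
  g <- gas_component(name)
  mu <- sw_viscosity(T, S)
  mu25 <- sw_viscosity(25, 0)
  g$D25 * ((T + 273.15) / 298.15) * (mu25 / mu)
}

#' Modified Henry's law solubility
#'
#' Equilibrium dissolved concentration of a gas at partial pressure `P`
#' (fugacity approximated by partial pressure, adequate at shelf depths
#' where fugacity coefficients stay near one), with a van 't Hoff
#' temperature dependence of the Henry constant and exponential
#' salting-out in salinity.
#'
#' @inheritParams gas_component
#' @inheritParams seawater
#' @param P partial pressure of the component, Pa.
#' @return equilibrium concentration, kg/m3.
#' @export
solubility <- function(name, T, S, P) {
  .check_TS(T, S)
  if (any(P < 0)) stop("partial pressure must be non-negative", call. = FALSE)
  g <- gas_component(name)
  TK <- T + 273.15
  kh <- g$kh_ref * exp(g$dlnkh_dinvT * (1 / TK - 1 / 298.15)) *
    exp(-g$k_salt * S)
  kh * P * g$M
}

#' Dissolved N2 and O2 at equilibrium with the atmosphere
#'
#' Ambient concentrations of nitrogen and oxygen assuming equilibrium with a
#' standard atmosphere at the sea surface, evaluated with the same Henry
#' functions that drive the bubble gas exchange and applied uniformly over
#' depth.
#'
#' @inheritParams seawater
#' @return named numeric vector (kg/m3) with elements `N2` and `O2`.
#' @export
equilibrium_dissolved_gases <- function(T, S) {
  .check_TS(T, S)
  c(N2 = solubility("N2", T, S, .atm_mole_fraction[["N2"]] * 101325),
    O2 = solubility("O2", T, S, .atm_mole_fraction[["O2"]] * 101325))
}
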