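#' Real-gas density by the Peng-Robinson equation of state
#'
#' Density of a CH4/N2/O2 gas mixture from the Peng-Robinson cubic equation
#' of state with classical van der Waals mixing rules (zero binary
#' interaction parameters, acceptable for these light gases) and the
#' Peneloux volume-translation correction, which removes most of the
#' systematic molar-volume bias of the untranslated equation.
#'
#' @param composition named numeric vector of mole fractions (or moles;
#'   normalized internally) over a subset of CH4, N2, O2.
#' @param T temperature, degrees C.
#' @param P absolute pressure, Pa.
#' @param volume_translation apply the Peneloux correction (default `TRUE`).
#' @return gas density, kg/m3.
#' @export
gas_density <- function(composition, T, P, volume_translation = TRUE) {
  if (is.null(names(composition)) || any(!names(composition) %in% c("CH4", "N2", "O2")))
    stop("composition must be named with components among CH4, N2, O2", call. = FALSE)
  if (any(composition < 0) || sum(composition) <= 0)
    stop("composition must be non-negative with positive total", call. = FALSE)
  if (!is.finite(T) || !is.finite(P) || P <= 0 || T < -100 || T > 300)
    stop("unphysical temperature or pressure", call. = FALSE)
  y <- composition / sum(composition)
  g <- gas_component(names(y))
  R <- 8.314462618
  TK <- T + 273.15

  kappa <- 0.37464 + 1.54226 * g$omega - 0.26992 * g$omega^2
  alpha <- (1 + kappa * (1 - sqrt(TK / g$Tc)))^2
  ai <- 0.45724 * R^2 * g$Tc^2 / g$Pc * alpha
  bi <- 0.07780 * R * g$Tc / g$Pc
  # van der Waals mixing, kij = 0
  a <- sum(outer(y * sqrt(ai), y * sqrt(ai)))
  b <- sum(y * bi)

  A <- a * P / (R * TK)^2
  B <- b * P / (R * TK)
  # P-R cubic in the compressibility factor Z
  coefs <- c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1)
  roots <- polyroot(coefs)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  real <- real[real > B]
  if (length(real) == 0) stop("no physical root of the P-R cubic", call. = FALSE)
  Z <- max(real)  # vapor branch

  v <- Z * R * TK / P  # molar volume, m3/mol
  if (volume_translation) {
    Z_RA <- 0.29056 - 0.08775 * g$omega
    ci <- 0.40768 * (R * g$Tc / g$Pc) * (0.29441 - Z_RA)
    v <- v - sum(y * ci)
  }
  sum(y * g$M) / v
}
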