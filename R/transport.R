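#' Air-sea mass transfer coefficient from wind speed
#'
#' Quadratic wind-speed parametrization of the gas-transfer (piston)
#' velocity, `kw = a * U10^2 * (Sc / 660)^(-1/2)`, with the empirical
#' coefficient `a = 6.97e-7 s/m` and the Schmidt number of methane in
#' seawater `Sc = 677`. The Schmidt-number factor is normalized to the
#' parametrization's reference value of 660.
#'
#' @param U10 wind speed at 10 m, m/s (vectorized).
#' @param a empirical coefficient, s/m.
#' @param Sc Schmidt number of the dissolved gas.
#' @return mass transfer coefficient, m/s.
#' @export
kw_from_wind <- function(U10, a = 6.97e-7, Sc = 677) {
  if (any(U10 < 0)) stop("wind speed must be non-negative", call. = FALSE)
  a * U10^2 * (Sc / 660)^(-0.5)
}

#' One Crank-Nicolson step (or several) with fixed coefficients
#'
#' Advances the dissolved-methane concentration by `n_steps` theta-weighted
#' finite-volume steps with constant face diffusivities, decay rate and
#' surface piston velocity, returning the step's biodegraded and ventilated
#' masses so the caller can close the budget. Diffusion is unconditionally
#' stable; `theta = 0.5` is Crank-Nicolson, `theta = 1` backward Euler.
#'
#' @param C concentration per cell, fraction per metre (surface first).
#' @param K_face diffusivities on the `length(C) - 1` interior faces, m2/s
#'   (a scalar or a cell-centre vector of length `length(C)` is averaged
#'   onto faces).
#' @param dz cell thickness, m.
#' @param dt time step, days.
#' @param k1 first-order decay rate, 1/day.
#' @param kw surface mass transfer coefficient, m/s.
#' @param n_steps number of steps.
#' @param theta implicitness weight in `[0.5, 1]`.
#' @param clip clip round-off negative concentrations (mass-neutrally).
#' @return list with `C`, `mass`, `biodegraded`, `ventilated`, `clipped`.
#' @export
cn_step <- function(C, K_face, dz = 1, dt = 0.01, k1 = 0, kw = 0,
                    n_steps = 1, theta = 0.5, clip = TRUE) {
  if (dt <= 0 || dz <= 0) stop("dt and dz must be positive", call. = FALSE)
  if (k1 < 0 || kw < 0) stop("k1 and kw must be non-negative", call. = FALSE)
  n <- length(C)
  if (length(K_face) == 1) K_face <- rep(K_face, n - 1)
  if (length(K_face) == n) K_face <- (K_face[-1] + K_face[-n]) / 2
  if (length(K_face) != n - 1) stop("K_face has incompatible length", call. = FALSE)
  .cn_kernel_steps(C, K_face * 86400, dz, dt, as.integer(n_steps), k1,
                   kw * 86400, theta, clip)
}

#' Run the diffusion-reaction model until the column is depleted
#'
#' Solves the vertical diffusion-reaction equation for dissolved methane
#' starting from a bubble deposition profile, with eddy diffusivity and wind
#' (hence piston velocity) interpolated in time from the scenario's daily
#' snapshots, wrapping periodically past the end of the year. The run
#' terminates when the dissolved fraction of released methane falls below
#' `stop_fraction`. Bookkeeping closes the budget
#' `dissolved + biodegraded + ventilated + bubble = 1` to round-off at every
#' output time.
#'
#' @param deposition a [deposition_profile()] (fractions of released
#'   methane per cell; carries the directly surfaced bubble fraction).
#' @param scenario a `seep_scenario` on the same grid.
#' @param k1 biodegradation rate, 1/day (or give `t12` instead).
#' @param t12 biodegradation half-life, days (alternative to `k1`).
#' @param start_day day of year at which the release occurs.
#' @param stop_fraction termination threshold on the dissolved fraction.
#' @param dt time step, days.
#' @param max_days horizon after which non-termination is an error.
#' @param out_every record the balance every this many steps.
#' @param a,Sc surface-exchange constants, see [kw_from_wind()].
#' @param theta implicitness weight.
#' @return a `mass_balance` data frame: `time` (days since release),
#'   `dissolved`, `biodegraded`, `ventilated`, `bubble` (all fractions of
#'   released methane); attributes `terminated`, `final_C`, `clipped`.
#' @export
run_until_depleted <- function(deposition, scenario, k1 = NULL, t12 = NULL,
                               start_day = 0, stop_fraction = 1e-7,
                               dt = 0.01, max_days = 20000, out_every = 100,
                               a = 6.97e-7, Sc = 677, theta = 0.5) {
  if (is.null(k1)) {
    if (is.null(t12)) stop("give k1 or t12", call. = FALSE)
    k1 <- halflife_to_rate(t12)
  }
  if (k1 < 0) stop("k1 must be non-negative", call. = FALSE)
  if (!inherits(deposition, "deposition_profile"))
    stop("deposition must be a deposition_profile", call. = FALSE)
  nz <- length(scenario$depth)
  if (nrow(deposition) != nz)
    stop("deposition grid does not match the scenario grid", call. = FALSE)
  dz <- scenario$dz
  C0 <- deposition$fraction / dz  # fraction per metre
  bubble <- attr(deposition, "surfaced")

  Kf_t <- (scenario$K[-1, , drop = FALSE] + scenario$K[-nz, , drop = FALSE]) / 2
  kw_t <- kw_from_wind(scenario$U10, a, Sc) * 86400  # m/day

  res <- .cn_kernel_run(C0, Kf_t * 86400, kw_t, scenario$year_days, dz, dt,
                        k1, start_day, stop_fraction, max_days,
                        as.integer(out_every), theta)
  if (!res$terminated)
    warning(sprintf(
      "column not depleted after %g days (dissolved fraction %.3e remaining)",
      max_days, res$dissolved[length(res$dissolved)]), call. = FALSE)
  out <- data.frame(time = res$time - start_day,
                    dissolved = res$dissolved,
                    biodegraded = res$biodegraded,
                    ventilated = res$ventilated,
                    bubble = bubble)
  attr(out, "terminated") <- res$terminated
  attr(out, "final_C") <- res$C
  attr(out, "clipped") <- res$clipped
  attr(out, "k1") <- k1
  attr(out, "start_day") <- start_day
  class(out) <- c("mass_balance", "data.frame")
  out
}

#' Terminal fate fractions of a depleted run
#'
#' Returns the (bubble, ventilated, biodegraded) split at the end of a
#' depletion run. The residual dissolved mass (at most the stop fraction)
#' is allocated proportionally to the cumulative biodegraded:ventilated
#' split so that the three fractions sum to one exactly.
#'
#' @param balance a `mass_balance` from [run_until_depleted()].
#' @return named numeric vector `bubble`, `ventilated`, `biodegraded`.
#' @export
terminal_fractions <- function(balance) {
  last <- balance[nrow(balance), ]
  sinks <- c(last$biodegraded, last$ventilated)
  share <- if (sum(sinks) > 0) sinks / sum(sinks) else c(0.5, 0.5)
  bio <- last$biodegraded + last$dissolved * share[1]
  vent <- last$ventilated + last$dissolved * share[2]
  tot <- bio + vent + last$bubble
  c(bubble = last$bubble / tot, ventilated = vent / tot, biodegraded = bio / tot)
}

#' Write a mass-balance series as CSV
#'
#' @param balance a `mass_balance`.
#' @param file CSV path.
#' @export
write_mass_balance_csv <- function(balance, file) {
  write.csv(as.data.frame(balance), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Observed convergence order of the transport scheme
#'
#' Measures the scheme's accuracy against the analytic decaying-cosine mode
#' `C(z, t) = cos(pi z / H) exp(-(K pi^2 / H^2 + k1) t)` on a closed column
#' (zero-flux at both ends, no surface exchange). For `which = "space"` the
#' grid and step are refined together against the exact solution; for
#' `which = "time"` the step alone is refined and the error is taken
#' against the exact solution of the semi-discrete system (whose decay rate
#' is the discrete eigenvalue of the finite-volume operator), isolating the
#' time discretization.
#'
#' @param which `"space"` or `"time"`.
#' @param H column depth, m.
#' @param K diffusivity, m2/s.
#' @param k1 decay rate, 1/day.
#' @param t_end integration time, days.
#' @param n_refine number of successive halvings.
#' @param nz0,dt0 coarsest resolution.
#' @param theta implicitness weight (0.5 CN, 1 backward Euler).
#' @return list with `orders` (successive observed orders), `order` (their
#'   mean), `errors` (max-norm errors per refinement).
#' @export
convergence_order <- function(which = c("space", "time"), H = 50, K = 1e-3,
                              k1 = 0.1, t_end = 0.5, n_refine = 4,
                              nz0 = 25, dt0 = 0.05, theta = 0.5) {
  which <- match.arg(which)
  Kday <- K * 86400
  errors <- numeric(n_refine)
  for (r in seq_len(n_refine)) {
    fac <- 2^(r - 1)
    nz <- if (which == "space") nz0 * fac else nz0 * 2^n_refine
    dt <- dt0 / fac
    dz <- H / nz
    zc <- seq(dz / 2, H - dz / 2, by = dz)
    C0 <- cos(pi * zc / H)
    n_steps <- round(t_end / dt)
    res <- cn_step(C0, rep(K, nz), dz = dz, dt = dt, k1 = k1, kw = 0,
                   n_steps = n_steps, theta = theta, clip = FALSE)
    lam_exact <- Kday * pi^2 / H^2
    # discrete eigenvalue of the FV operator for the cosine mode
    lam_disc <- Kday * 2 * (1 - cos(pi * dz / H)) / dz^2
    lam <- if (which == "time") lam_disc else lam_exact
    ref <- C0 * exp(-(lam + k1) * t_end)
    errors[r] <- max(abs(res$C - ref))
  }
  orders <- log2(errors[-n_refine] / errors[-1])
  if (any(diff(errors) > 0))
    warning("error sequence is not monotone decreasing", call. = FALSE)
  list(orders = orders, order = mean(orders), errors = errors)
}
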