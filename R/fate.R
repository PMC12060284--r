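#' Normalized ventilation rate of the water column
#'
#' The ventilation rate `v = Mdot_atm / M` is the instantaneous fraction of
#' the dissolved methane mass that escapes through the surface per unit
#' time. It has the same units (1/day) as the first-order biodegradation
#' rate `k1`, so the two are directly comparable: their ratio sets the
#' branching between ventilation and biodegradation. `v` is computed as a
#' finite-difference rate from the cumulative ventilated mass of a run and
#' is masked (`NA`) where the dissolved mass is below `mass_floor`.
#'
#' @param balance a `mass_balance` from [run_until_depleted()].
#' @param mass_floor dissolved-mass floor below which `v` is masked.
#' @return data frame of class `ventilation_series`: `time` (interval
#'   midpoints, days), `v` (1/day), `M` (dissolved fraction),
#'   `Mdot_atm` (fraction/day).
#' @export
ventilation_rate <- function(balance, mass_floor = 1e-9) {
  if (nrow(balance) < 2) stop("balance series too short", call. = FALSE)
  dt <- diff(balance$time)
  Mdot <- diff(balance$ventilated) / dt
  M <- (balance$dissolved[-1] + balance$dissolved[-nrow(balance)]) / 2
  v <- ifelse(M > mass_floor, Mdot / M, NA_real_)
  structure(data.frame(time = balance$time[-1] - dt / 2, v = v, M = M,
                       Mdot_atm = Mdot),
            class = c("ventilation_series", "data.frame"))
}

#' Ventilated share of dissolved mass in the well-mixed box model
#'
#' Closed-form oracle for a permanently well-mixed column of depth `H` with
#' piston velocity `kw` and decay `k1`: ventilation proceeds at rate `kw/H`
#' and biodegradation at `k1`, so the terminal ventilated share of the
#' dissolved mass is `(kw/H) / (kw/H + k1)`.
#'
#' @param kw piston velocity, m/day (any time unit, consistent with `k1`).
#' @param H column depth, m.
#' @param k1 decay rate in the same time unit as `kw/H`.
#' @return ventilated share, in `[0, 1]`.
#' @export
box_model_fraction <- function(kw, H, k1) {
  if (kw < 0 || k1 < 0 || H <= 0) stop("kw, k1 >= 0 and H > 0 required", call. = FALSE)
  if (kw == 0 && k1 == 0) stop("kw and k1 cannot both be zero", call. = FALSE)
  (kw / H) / (kw / H + k1)
}

#' Annual ensemble of depletion runs
#'
#' Runs `n_starts` depletion simulations with release dates evenly spaced
#' through the year (the environment wraps around past year end), each until
#' the dissolved fraction drops below `stop_fraction`, and averages the
#' terminal fate fractions. Deterministic given the scenario.
#'
#' @inheritParams run_until_depleted
#' @param n_starts number of ensemble members (default 36).
#' @param ... passed on to [run_until_depleted()].
#' @return list with `mean` (named fractions: bubble, ventilated,
#'   biodegraded) and `members` (data frame of per-start fractions).
#' @export
annual_ensemble <- function(deposition, scenario, k1 = NULL, t12 = NULL,
                            n_starts = 36, stop_fraction = 1e-7, ...) {
  if (is.null(k1)) {
    if (is.null(t12)) stop("give k1 or t12", call. = FALSE)
    k1 <- halflife_to_rate(t12)
  }
  starts <- (seq_len(n_starts) - 1) * scenario$year_days / n_starts
  members <- vapply(starts, function(s) {
    bal <- run_until_depleted(deposition, scenario, k1 = k1, start_day = s,
                              stop_fraction = stop_fraction, ...)
    if (!attr(bal, "terminated"))
      stop(sprintf("ensemble member starting day %.1f did not terminate", s),
           call. = FALSE)
    terminal_fractions(bal)
  }, numeric(3))
  members <- as.data.frame(t(members))
  members$start_day <- starts
  list(mean = c(bubble = mean(members$bubble),
                ventilated = mean(members$ventilated),
                biodegraded = mean(members$biodegraded)),
       members = members[, c("start_day", "bubble", "ventilated", "biodegraded")])
}

#' Fate branching as a function of biodegradation half-life
#'
#' Sweeps the biodegradation half-life over a (log-spaced by default) grid,
#' running the annual ensemble at each value, and collects the annual
#' average fate split. The direct-bubble fraction is independent of the
#' half-life; the biodegraded fraction decreases with increasing half-life.
#'
#' @inheritParams annual_ensemble
#' @param halflife_days half-life grid, days; default 25 log-spaced values
#'   on `[1, 1000]`.
#' @return object of class `fate_summary`: data frame with columns
#'   `halflife_days`, `frac_bubble`, `frac_ventilated`, `frac_biodegraded`;
#'   per-member fractions in attribute `members` (list per half-life).
#' @export
halflife_sweep <- function(deposition, scenario,
                           halflife_days = 10^seq(0, 3, length.out = 25),
                           n_starts = 36, ...) {
  if (any(halflife_days <= 0)) stop("half-lives must be positive", call. = FALSE)
  rows <- vector("list", length(halflife_days))
  members <- vector("list", length(halflife_days))
  for (i in seq_along(halflife_days)) {
    ens <- annual_ensemble(deposition, scenario, t12 = halflife_days[i],
                           n_starts = n_starts, ...)
    rows[[i]] <- data.frame(halflife_days = halflife_days[i],
                            frac_bubble = ens$mean[["bubble"]],
                            frac_ventilated = ens$mean[["ventilated"]],
                            frac_biodegraded = ens$mean[["biodegraded"]])
    members[[i]] <- ens$members
  }
  out <- do.call(rbind, rows)
  attr(out, "members") <- members
  class(out) <- c("fate_summary", "data.frame")
  out
}

#' Write a fate summary as CSV
#'
#' @param summary a `fate_summary`.
#' @param file CSV path.
#' @export
write_fate_summary_csv <- function(summary, file) {
  write.csv(as.data.frame(summary), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
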