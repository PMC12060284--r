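#' First-order biodegradation kinetics of dissolved methane
#'
#' Parameter container for the tracer-experiment generating model. In the
#' incubations, tritium-labelled methane is oxidized to labelled water, so
#' the measured (sparged) activity starts at the sterile-control background
#' `Cb` at time zero and rises asymptotically toward the pre-incubation
#' total `Ctot` as methane is consumed with a concentration-independent
#' half-life. Temperature enters through a Q10 scaling of the half-life;
#' activities are normalized by the mean control background, so `Cb` and
#' `Ctot` are dimensionless.
#'
#' @param t12_ref biodegradation half-life at `T_ref`, days.
#' @param Cb background activity (normalized).
#' @param Ctot total activity (normalized); must exceed `Cb` for a
#'   meaningful fit.
#' @param ln_sigma log of the Gaussian observation noise scale.
#' @param Q10 temperature coefficient (fixed, not estimated).
#' @param T_ref reference temperature, degC.
#' @return list of class `kinetics_params`.
#' @export
kinetics_params <- function(t12_ref, Cb, Ctot, ln_sigma = log(0.1),
                            Q10 = 2, T_ref = 5) {
  if (t12_ref <= 0) stop("t12_ref must be positive", call. = FALSE)
  if (Cb < 0 || Ctot < 0) stop("Cb and Ctot must be non-negative", call. = FALSE)
  if (Q10 <= 0) stop("Q10 must be positive", call. = FALSE)
  structure(list(t12_ref = t12_ref, Cb = Cb, Ctot = Ctot,
                 ln_sigma = ln_sigma, Q10 = Q10, T_ref = T_ref),
            class = "kinetics_params")
}

#' Q10 temperature scaling of the half-life
#'
#' `t12(T) = t12_ref * Q10^(-(T - T_ref) / 10)`: with Q10 = 2, a 10 degC
#' warming halves the half-life (doubles the rate).
#'
#' @param t12_ref half-life at the reference temperature, days.
#' @param T temperature, degC.
#' @param Q10 temperature coefficient.
#' @param T_ref reference temperature, degC.
#' @return half-life at `T`, days.
#' @export
scale_halflife <- function(t12_ref, T, Q10 = 2, T_ref = 5) {
  if (any(t12_ref <= 0)) stop("t12_ref must be positive", call. = FALSE)
  if (any(Q10 <= 0)) stop("Q10 must be positive", call. = FALSE)
  t12_ref * Q10^(-(T - T_ref) / 10)
}

#' Convert between half-life and first-order rate coefficient
#'
#' `k1 = ln(2) / t12`; the two functions are mutual inverses.
#'
#' @param t12 half-life, days.
#' @param k1 rate coefficient, 1/day.
#' @return the converted quantity.
#' @export
halflife_to_rate <- function(t12) {
  if (any(t12 <= 0)) stop("half-life must be positive", call. = FALSE)
  log(2) / t12
}

#' @rdname halflife_to_rate
#' @export
rate_to_halflife <- function(k1) {
  if (any(k1 <= 0)) stop("rate must be positive", call. = FALSE)
  log(2) / k1
}

#' Expected normalized activity of the tracer experiment
#'
#' Generating-model mean: `C(t; T) = Ctot - (Ctot - Cb) * 2^(-t / t12(T))`,
#' i.e. background at t = 0, half the gap closed after one (temperature
#' scaled) half-life, asymptote at `Ctot`. No lag phase is assumed.
#'
#' @param params a [kinetics_params()].
#' @param t incubation time, days (vectorized).
#' @param T incubation temperature, degC (scalar or same length as `t`).
#' @return expected activity (normalized, dimensionless).
#' @export
predict_activity <- function(params, t, T = params$T_ref) {
  if (!inherits(params, "kinetics_params")) stop("params must be kinetics_params", call. = FALSE)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  t12 <- scale_halflife(params$t12_ref, T, params$Q10, params$T_ref)
  params$Ctot - (params$Ctot - params$Cb) * 2^(-t / t12)
}

# model mean per dataset row: tests follow the decay curve; sterile controls
# observe Cb directly, pre-incubation samples observe Ctot
.model_mean <- function(params, data) {
  mu <- numeric(nrow(data))
  is_test <- data$kind == "test"
  if (any(is_test))
    mu[is_test] <- predict_activity(params, data$day[is_test],
                                    data$temperature_C[is_test])
  mu[data$kind == "control"] <- params$Cb
  mu[data$kind == "pre"] <- params$Ctot
  mu
}

#' Gaussian log-likelihood of a tracer dataset
#'
#' Log-probability of the observed activities given the kinetics parameters,
#' with a single shared noise scale `s_n = exp(ln_sigma)` across all flasks
#' (test, sterile-control and pre-incubation samples alike).
#'
#' @param params a [kinetics_params()].
#' @param data a tracer dataset (see [simulate_tracer_experiment()]).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  .check_tracer_data(data)
  mu <- .model_mean(params, data)
  s <- exp(params$ln_sigma)
  r <- data$activity_normalized - mu
  n <- length(r)
  -n / 2 * log(2 * pi) - n * params$ln_sigma - sum(r^2) / (2 * s^2)
}

.check_tracer_data <- function(data) {
  need <- c("day", "temperature_C", "replicate", "kind", "activity_normalized")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("tracer data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0) stop("tracer dataset is empty", call. = FALSE)
  invisible(TRUE)
}
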