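#' Design of a tritium-tracer incubation experiment
#'
#' Describes the layout the simulator reproduces: flasks incubated for a set
#' of sampling days at one or more temperatures, plus sterile-control
#' (background, `Cb`) and pre-incubation (total activity, `Ctot`) samples.
#' The defaults mirror the study conditions: sampling at 2, 4, 13, 17 and
#' 27 days; two replicate series at 5 degC and one at 8.5 degC; truth taken
#' at the posterior-median-like parameter point.
#'
#' @param sampling_days incubation durations, days.
#' @param temperatures incubation temperatures, degC.
#' @param replicates flasks per (day, temperature) condition; scalar or one
#'   entry per temperature.
#' @param n_control number of sterile-control samples.
#' @param n_pre number of pre-incubation samples.
#' @param true_params generating [kinetics_params()].
#' @param noise_scale Gaussian noise sd on normalized activities; defaults
#'   to `exp(true_params$ln_sigma)`.
#' @return list of class `tracer_design`.
#' @export
tracer_design <- function(sampling_days = c(2, 4, 13, 17, 27),
                          temperatures = c(5, 8.5),
                          replicates = c(2, 1),
                          n_control = 3, n_pre = 3,
                          true_params = kinetics_params(
                            t12_ref = 11.622, Cb = 0.461, Ctot = 3.883,
                            ln_sigma = -0.133),
                          noise_scale = NULL) {
  if (any(sampling_days < 0)) stop("sampling days must be non-negative", call. = FALSE)
  replicates <- rep_len(replicates, length(temperatures))
  if (any(replicates < 1)) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(noise_scale)) noise_scale <- exp(true_params$ln_sigma)
  if (noise_scale < 0) stop("noise_scale must be non-negative", call. = FALSE)
  structure(list(sampling_days = sampling_days, temperatures = temperatures,
                 replicates = replicates, n_control = n_control, n_pre = n_pre,
                 true_params = true_params, noise_scale = noise_scale),
            class = "tracer_design")
}

#' Simulate a tracer experiment
#'
#' Draws one activity value per flask from the generating model: the
#' Q10-scaled exponential-approach mean at the flask's day and temperature,
#' plus Gaussian noise of scale `design$noise_scale`. Sterile controls are
#' noisy observations of `Cb` and pre-incubation samples of `Ctot`, sharing
#' the same noise model. With `noise_scale = 0` the data lie exactly on the
#' model curve.
#'
#' @param design a [tracer_design()].
#' @param seed integer RNG seed.
#' @return data frame with columns `day`, `temperature_C`, `replicate`,
#'   `kind` (`test`, `control`, `pre`), `activity_normalized`; the design is
#'   attached as attribute `"design"`.
#' @export
simulate_tracer_experiment <- function(design = tracer_design(), seed = 1) {
  if (!inherits(design, "tracer_design")) stop("design must be a tracer_design", call. = FALSE)
  grid <- do.call(rbind, lapply(seq_along(design$temperatures), function(i) {
    expand.grid(day = design$sampling_days,
                temperature_C = design$temperatures[i],
                replicate = seq_len(design$replicates[i]))
  }))
  tests <- data.frame(grid, kind = "test")
  extras <- data.frame(
    day = 0,
    temperature_C = design$true_params$T_ref,
    replicate = c(seq_len(design$n_control), seq_len(design$n_pre)),
    kind = rep(c("control", "pre"), c(design$n_control, design$n_pre)))
  data <- rbind(tests, extras)
  mu <- .model_mean(design$true_params, transform(data, activity_normalized = 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  data$activity_normalized <- mu + rnorm(nrow(data), 0, design$noise_scale)
  rownames(data) <- NULL
  attr(data, "design") <- design
  data
}

#' Write / read a tracer dataset as CSV
#'
#' @param data tracer dataset data frame.
#' @param file CSV path.
#' @return `read_tracer_csv` returns the data frame.
#' @export
write_tracer_csv <- function(data, file) {
  .check_tracer_data(data)
  write.csv(data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_tracer_csv
#' @export
read_tracer_csv <- function(file) {
  data <- read.csv(file)
  .check_tracer_data(data)
  data
}
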