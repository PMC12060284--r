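#' Configuration for a synthetic water-column scenario
#'
#' Parameters of the parametric seasonal environment: a water column that is
#' well mixed (high, near-uniform eddy diffusivity) in winter and develops a
#' summer pycnocline — a low-diffusivity band separating a warm surface mixed
#' layer from the cooler interior — from roughly May to October. The defaults
#' describe a shallow Norwegian-shelf station; deep stations that never mix
#' to the bottom are obtained by setting `mld_winter` below the station depth
#' and reducing `k_interior`.
#'
#' @param k_mixed eddy diffusivity of actively mixed water, m2/s.
#' @param k_pycnocline minimum diffusivity inside the pycnocline, m2/s.
#' @param k_interior diffusivity of the deep interior in the stratified
#'   season (and below `mld_winter` in winter), m2/s.
#' @param k_ceiling upper clamp on the diffusivity field, m2/s.
#' @param mld_summer summer surface mixed-layer depth, m.
#' @param mld_winter winter mixed-layer depth, m (`Inf` = mixed to bottom).
#' @param pycnocline_thickness vertical extent of the low-K band, m.
#' @param summer_onset,summer_end day-of-year bounds of full stratification.
#' @param ramp_days width of the smooth spring/autumn transitions, days.
#' @param T_deep,S_deep interior temperature (degC) and salinity (ppt).
#' @param T_summer_anomaly summer surface warming, degC.
#' @param S_summer_anomaly summer surface freshening, ppt (negative).
#' @param wind_mean,wind_sd mean and standard deviation of the 10 m wind
#'   speed, m/s.
#' @param wind_ar1 lag-1 day autocorrelation of the wind process.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(k_mixed = 0.1,
                            k_pycnocline = 1e-5,
                            k_interior = 1e-3,
                            k_ceiling = 0.2,
                            mld_summer = 20,
                            mld_winter = Inf,
                            pycnocline_thickness = 10,
                            summer_onset = 130,
                            summer_end = 290,
                            ramp_days = 30,
                            T_deep = 7,
                            S_deep = 34,
                            T_summer_anomaly = 7,
                            S_summer_anomaly = -0.5,
                            wind_mean = 8,
                            wind_sd = 3,
                            wind_ar1 = 0.7) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all configuration entries must be numeric", call. = FALSE)
  for (key in c("k_mixed", "k_pycnocline", "k_interior", "k_ceiling",
                "mld_summer", "pycnocline_thickness", "ramp_days",
                "wind_mean", "wind_sd"))
    if (cfg[[key]] < 0) stop("negative value for ", key, call. = FALSE)
  structure(cfg, class = "scenario_config")
}

# seasonal stratification weight in [0, 1]: 0 in winter, 1 in full summer,
# smooth cosine ramps of width ramp_days on both sides; periodic in the year
.season_weight <- function(t, config, period = 365) {
  t <- t %% period
  up <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))
  w_on <- up((t - (config$summer_onset - config$ramp_days)) / config$ramp_days)
  w_off <- up(((config$summer_end + config$ramp_days) - t) / config$ramp_days)
  pmin(w_on, w_off)
}

# mixed-layer depth trajectory; winter value is pushed safely below the
# sea floor when the column mixes to the bottom
.mld_of_time <- function(t, config, station_depth, period = 365) {
  w <- .season_weight(t, config, period)
  mld_w <- min(config$mld_winter, station_depth + 5 * config$pycnocline_thickness)
  w * config$mld_summer + (1 - w) * mld_w
}

#' Synthetic seasonal eddy-diffusivity field
#'
#' Builds a depth-by-time eddy diffusivity field K(z, t) with a high,
#' near-uniform column in winter and a summer structure of mixed surface
#' layer / low-K pycnocline / weakly mixed interior. The vertical structure
#' is composed in log10(K) with tanh transitions so that faces are smooth;
#' values are clamped to `[0, k_ceiling]`.
#'
#' @param depth_grid cell-centre depths, m, strictly increasing, positive down.
#' @param time_grid times, days since year start, strictly increasing.
#' @param config a [scenario_config()].
#' @param station_depth sea-floor depth, m; defaults to the last cell edge
#'   implied by `depth_grid` (uniform cells assumed).
#' @return matrix `length(depth_grid)` x `length(time_grid)`, m2/s.
#' @export
make_seasonal_diffusivity <- function(depth_grid, time_grid, config = scenario_config(),
                                      station_depth = NULL) {
  if (is.unsorted(depth_grid, strictly = TRUE))
    stop("depth_grid must be strictly increasing", call. = FALSE)
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("time_grid must be strictly increasing", call. = FALSE)
  if (is.null(station_depth)) {
    dz <- if (length(depth_grid) > 1) diff(depth_grid)[1] else 2 * depth_grid[1]
    station_depth <- depth_grid[length(depth_grid)] + dz / 2
  }
  lg_mix <- log10(config$k_mixed)
  lg_pyc <- log10(config$k_pycnocline)
  lg_int <- log10(config$k_interior)
  wtrans <- config$pycnocline_thickness / 4
  K <- matrix(0, length(depth_grid), length(time_grid))
  for (j in seq_along(time_grid)) {
    mld <- .mld_of_time(time_grid[j], config, station_depth)
    s1 <- 0.5 * (1 + tanh((depth_grid - mld) / wtrans))
    s2 <- 0.5 * (1 + tanh((depth_grid - (mld + config$pycnocline_thickness)) / wtrans))
    lg <- lg_mix + s1 * (lg_pyc - lg_mix) + s2 * (lg_int - lg_pyc)
    K[, j] <- pmin(10^lg, config$k_ceiling)
  }
  K
}

# smooth seasonal surface-anomaly field shared by temperature and salinity
.surface_anomaly_field <- function(depth_grid, time_grid, config, station_depth, anomaly) {
  A <- matrix(0, length(depth_grid), length(time_grid))
  wtrans <- config$pycnocline_thickness / 4
  for (j in seq_along(time_grid)) {
    w <- .season_weight(time_grid[j], config)
    mld <- .mld_of_time(time_grid[j], config, station_depth)
    shape <- 1 - 0.5 * (1 + tanh((depth_grid - mld) / wtrans))
    A[, j] <- w * anomaly * shape
  }
  A
}

#' Synthetic wind-speed series
#'
#' Clipped AR(1) process for the 10 m wind speed: stationary mean
#' `wind_mean`, marginal standard deviation `wind_sd`, daily lag-1
#' autocorrelation `wind_ar1`, truncated at zero. Reproducible for a fixed
#' seed; `wind_sd = 0` gives a constant series.
#'
#' @inheritParams make_seasonal_diffusivity
#' @param seed integer RNG seed.
#' @return numeric vector of wind speeds, m/s, one per time point.
#' @export
make_wind_series <- function(time_grid, seed, config = scenario_config()) {
  if (config$wind_mean < 0 || config$wind_sd < 0)
    stop("wind mean and standard deviation must be non-negative", call. = FALSE)
  n <- length(time_grid)
  if (config$wind_sd == 0) return(rep(config$wind_mean, n))
  phi <- config$wind_ar1
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, config$wind_sd)
  innov_sd <- config$wind_sd * sqrt(1 - phi^2)
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, innov_sd)
  pmax(config$wind_mean + x, 0)
}

# save/restore the global RNG state so generators are pure given a seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a synthetic water-column scenario
#'
#' Builds the full environment the fate chain consumes: seasonal eddy
#' diffusivity, temperature and salinity fields on a shared (depth, time)
#' grid, and a wind time series. Cells are 1 m thick and snapshots daily by
#' default, matching the per-metre deposition reporting of the bubble stage.
#'
#' @param station_depth sea-floor depth, m.
#' @param config a [scenario_config()].
#' @param seed integer seed for the wind series.
#' @param dz cell thickness, m.
#' @param dt_days snapshot interval, days.
#' @param year_days length of the (periodic) year, days.
#' @return an object of class `seep_scenario`: list with `depth` (cell
#'   centres, m), `time` (days), `K`, `T`, `S` (depth x time matrices),
#'   `U10` (per time), `station_depth`, `config`, `seed`.
#' @export
make_scenario <- function(station_depth, config = scenario_config(), seed = 1,
                          dz = 1, dt_days = 1, year_days = 365) {
  if (station_depth <= 0) stop("station_depth must be positive", call. = FALSE)
  depth <- seq(dz / 2, station_depth - dz / 2, by = dz)
  time <- seq(0, year_days - dt_days, by = dt_days)
  K <- make_seasonal_diffusivity(depth, time, config, station_depth)
  T <- config$T_deep + .surface_anomaly_field(depth, time, config, station_depth,
                                              config$T_summer_anomaly)
  S <- config$S_deep + .surface_anomaly_field(depth, time, config, station_depth,
                                              config$S_summer_anomaly)
  U10 <- make_wind_series(time, seed, config)
  structure(list(depth = depth, time = time, K = K, T = T, S = S, U10 = U10,
                 station_depth = station_depth, dz = dz,
                 year_days = year_days, config = config, seed = seed),
            class = "seep_scenario")
}

#' @export
print.seep_scenario <- function(x, ...) {
  cat("<seep_scenario>\n")
  cat(sprintf("  station depth: %g m (%d cells of %g m)\n",
              x$station_depth, length(x$depth), x$dz))
  cat(sprintf("  time: %d snapshots over %g days\n", length(x$time), x$year_days))
  cat(sprintf("  K range: [%.2e, %.2e] m2/s; mean wind %.1f m/s\n",
              min(x$K), max(x$K), mean(x$U10)))
  invisible(x)
}

#' Extract one time slice of a scenario as an ambient profile
#'
#' @param scenario a `seep_scenario`.
#' @param day day of year (interpolated linearly, periodic).
#' @return data frame with columns `depth`, `T`, `S`, `K`.
#' @export
scenario_profile <- function(scenario, day) {
  tt <- day %% scenario$year_days
  idx <- findInterval(tt, scenario$time)
  n <- length(scenario$time)
  i0 <- if (idx < 1) n else idx
  i1 <- if (i0 == n) 1 else i0 + 1
  t0 <- scenario$time[i0]
  span <- (scenario$time[min(i0 + 1, n)] - t0)
  if (i0 == n) span <- scenario$year_days - t0
  w <- if (span > 0) ((tt - t0) %% scenario$year_days) / span else 0
  blend <- function(M) (1 - w) * M[, i0] + w * M[, i1]
  data.frame(depth = scenario$depth, T = blend(scenario$T),
             S = blend(scenario$S), K = blend(scenario$K))
}

#' Write / read a scenario as plain-text files
#'
#' Serializes the environment as a long-format CSV of the gridded fields
#' (`depth, time, K, T, S`), a CSV of the wind series, and a YAML header with
#' scalar metadata and units, in one directory. The round trip restores the
#' scenario exactly (up to numeric text formatting, 15 significant digits).
#'
#' @param scenario a `seep_scenario`.
#' @param path directory to write into (created if needed).
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns the scenario.
#' @export
write_scenario <- function(scenario, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nz <- length(scenario$depth); nt <- length(scenario$time)
  fields <- data.frame(
    depth = rep(scenario$depth, times = nt),
    time = rep(scenario$time, each = nz),
    K = as.vector(scenario$K), T = as.vector(scenario$T),
    S = as.vector(scenario$S))
  write.csv(format(fields, digits = 15, trim = TRUE, scientific = NA),
            file.path(path, "fields.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(time = scenario$time, U10 = scenario$U10),
            file.path(path, "wind.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(station_depth = scenario$station_depth, dz = scenario$dz,
               year_days = scenario$year_days, seed = scenario$seed,
               units = list(depth = "m", time = "days", K = "m2/s",
                            T = "degC", S = "ppt", U10 = "m/s"),
               config = unclass(scenario$config))
  yaml::write_yaml(meta, file.path(path, "scenario.yaml"))
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "scenario.yaml"))
  fields <- read.csv(file.path(path, "fields.csv"))
  wind <- read.csv(file.path(path, "wind.csv"))
  depth <- sort(unique(fields$depth))
  time <- sort(unique(fields$time))
  ord <- order(fields$time, fields$depth)
  shape <- function(v) matrix(v[ord], length(depth), length(time))
  cfg <- do.call(scenario_config, meta$config)
  structure(list(depth = depth, time = time, K = shape(fields$K),
                 T = shape(fields$T), S = shape(fields$S), U10 = wind$U10,
                 station_depth = meta$station_depth, dz = meta$dz,
                 year_days = meta$year_days, config = cfg, seed = meta$seed),
            class = "seep_scenario")
}
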