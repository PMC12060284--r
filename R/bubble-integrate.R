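#' Integrate a single rising methane bubble
#'
#' Tracks one bubble released at the sea floor: rise at the terminal
#' velocity for its evolving size and shape, expansion from the ambient
#' pressure drop (Peng-Robinson density), dissolution of methane into the
#' water, and influx of dissolved nitrogen and oxygen. Ambient dissolved
#' methane is zero; N2 and O2 are at atmospheric equilibrium. Integration
#' (deSolve, `lsodar`) stops when the bubble reaches the surface or its
#' equivalent diameter falls below `d_floor`, in which case the remaining
#' methane is deposited in the current cell. The methane lost between output
#' points is binned conservatively onto a 1 m (by default) transport grid,
#' yielding the fraction-dissolved-per-metre deposition profile and the
#' directly surfaced fraction, which sum to one to round-off.
#'
#' @param release_depth release depth, m.
#' @param d0 initial equivalent spherical diameter, m (default 4.5 mm).
#' @param profile ambient profile: data frame with columns `depth`, `T`,
#'   `S` covering `[0, release_depth]`, or a `seep_scenario` (use `day`).
#' @param day day of year at which to slice a scenario profile.
#' @param dz deposition grid cell thickness, m.
#' @param d_floor termination diameter, m.
#' @param dt_out output (and binning) interval, s.
#' @param kL_scale multiplier on all bubble-water mass transfer
#'   coefficients (0 switches gas exchange off).
#' @param t_max integration horizon, s.
#' @return list of class `bubble_run` with elements `trajectory` (data frame:
#'   time_s, depth, diameter, velocity, regime, mole fractions, moles) and
#'   `deposition` (a `deposition_profile`).
#' @export
integrate_bubble <- function(release_depth, d0 = 4.5e-3, profile, day = 15,
                             dz = 1, d_floor = 5e-5, dt_out = 1,
                             kL_scale = 1, t_max = NULL) {
  if (inherits(profile, "seep_scenario")) {
    if (release_depth > profile$station_depth)
      stop("release depth exceeds station depth", call. = FALSE)
    profile <- scenario_profile(profile, day)
  }
  if (!all(c("depth", "T", "S") %in% names(profile)))
    stop("profile needs columns depth, T, S", call. = FALSE)
  if (release_depth <= 0 || d0 <= 0) stop("depth and d0 must be positive", call. = FALSE)
  if (is.null(t_max)) t_max <- max(3600, 20 * release_depth)

  gases <- gas_component(c("CH4", "N2", "O2"))
  T_fun <- approx_profile(profile$depth, profile$T)
  S_fun <- approx_profile(profile$depth, profile$S)
  amb <- t(vapply(seq_len(nrow(profile)),
                  function(i) equilibrium_dissolved_gases(profile$T[i], profile$S[i]),
                  numeric(2)))
  ambN2_fun <- approx_profile(profile$depth, amb[, 1])
  ambO2_fun <- approx_profile(profile$depth, amb[, 2])

  state_props <- function(z, n) {
    Tz <- T_fun(z); Sz <- S_fun(z)
    P <- pressure_at_depth(z)
    comp <- setNames(pmax(n, 0), gases$name)
    rho_g <- gas_density(comp, Tz, P)
    m <- sum(pmax(n, 0) * gases$M)
    V <- m / rho_g
    de <- (6 * V / pi)^(1 / 3)
    fp <- fluid_properties(Tz, Sz, rho_g)
    regime <- shape_regime(de, fp)
    u <- rise_velocity(de, fp, regime)
    list(T = Tz, S = Sz, P = P, de = de, u = u, regime = regime, fp = fp,
         comp = comp)
  }

  deriv <- function(t, y, parms) {
    z <- max(y[1], 0)
    n <- pmax(y[2:4], 0)
    if (sum(n) <= 0) return(list(rep(0, 4)))
    sp <- state_props(z, n)
    x <- n / sum(n)
    p_i <- x * sp$P
    Cs <- vapply(seq_len(3), function(i)
      solubility(gases$name[i], sp$T, sp$S, p_i[i]), numeric(1))
    Camb <- c(0, ambN2_fun(z), ambO2_fun(z))
    D <- molecular_diffusivity(gases$name, sp$T, sp$S)
    kL <- kL_scale * mass_transfer_coeff(sp$de, sp$regime, sp$u, D)
    A <- pi * sp$de^2
    dn <- -kL * A * (Cs - Camb) / gases$M
    list(c(-sp$u, dn))
  }

  root <- function(t, y, parms) {
    n <- pmax(y[2:4], 0)
    de <- if (sum(n) > 0) state_props(max(y[1], 0), n)$de else 0
    c(y[1], de - d_floor)
  }

  # initial moles of pure methane at the release condition
  T0 <- T_fun(release_depth); P0 <- pressure_at_depth(release_depth)
  rho0 <- gas_density(c(CH4 = 1), T0, P0)
  n0 <- rho0 * pi / 6 * d0^3 / gases$M[1]
  y0 <- c(z = release_depth, CH4 = n0, N2 = 0, O2 = 0)

  times <- seq(0, t_max, by = dt_out)
  sol <- deSolve::lsodar(y0, times, deriv, parms = NULL, rootfunc = root,
                         rtol = 1e-8, atol = n0 * 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("bubble integration failed near depth %.2f m", sol[nrow(sol), "z"]),
         call. = FALSE)
  sol <- as.data.frame(sol)
  terminated_at_surface <- sol$z[nrow(sol)] <= 1e-6

  traj <- do.call(rbind, lapply(seq_len(nrow(sol)), function(i) {
    n <- pmax(as.numeric(sol[i, c("CH4", "N2", "O2")]), 0)
    if (sum(n) <= 0) return(NULL)
    sp <- state_props(max(sol$z[i], 0), n)
    data.frame(time_s = sol$time[i], depth = sol$z[i], diameter = sp$de,
               velocity = sp$u, regime = sp$regime,
               x_CH4 = n[1] / sum(n), x_N2 = n[2] / sum(n), x_O2 = n[3] / sum(n),
               n_CH4 = n[1], n_N2 = n[2], n_O2 = n[3])
  }))

  deposition <- .bin_deposition(traj, n0, release_depth, dz,
                                surfaced = terminated_at_surface)
  structure(list(trajectory = traj, deposition = deposition,
                 release_depth = release_depth, d0 = d0), class = "bubble_run")
}

# linear interpolation clamped to the profile's end values
approx_profile <- function(x, y) {
  if (length(x) == 1) return(function(z) rep(y, length(z)))
  f <- approxfun(x, y, rule = 2)
  f
}

# distribute the methane lost between successive trajectory points onto the
# 1 m grid, proportionally to the depth overlap of each step with each cell
.bin_deposition <- function(traj, n0, release_depth, dz, surfaced) {
  edges <- seq(0, ceiling(release_depth / dz) * dz, by = dz)
  ncell <- length(edges) - 1
  frac <- numeric(ncell)
  z <- pmin(pmax(traj$depth, 0), release_depth)
  nch4 <- traj$n_CH4
  for (i in seq_len(nrow(traj) - 1)) {
    dn <- nch4[i] - nch4[i + 1]
    if (dn <= 0) next
    zt <- min(z[i], z[i + 1]); zb <- max(z[i], z[i + 1])
    if (zb - zt < 1e-12) {
      cell <- min(max(floor(zt / dz) + 1, 1), ncell)
      frac[cell] <- frac[cell] + dn
    } else {
      lo <- max(floor(zt / dz) + 1, 1)
      hi <- min(floor((zb - 1e-12) / dz) + 1, ncell)
      for (cell in lo:hi) {
        ov <- min(zb, edges[cell + 1]) - max(zt, edges[cell])
        frac[cell] <- frac[cell] + dn * ov / (zb - zt)
      }
    }
  }
  n_end <- nch4[length(nch4)]
  if (surfaced) {
    surfaced_frac <- n_end / n0
  } else {
    # bubble reached the termination floor: deposit the remainder locally
    cell <- min(max(floor(z[length(z)] / dz) + 1, 1), ncell)
    frac[cell] <- frac[cell] + n_end
    surfaced_frac <- 0
  }
  frac <- frac / n0
  # close the budget exactly: any residual from binning round-off goes to
  # the largest cell
  resid <- 1 - sum(frac) - surfaced_frac
  frac[which.max(frac)] <- frac[which.max(frac)] + resid
  deposition_profile(edges[-length(edges)], edges[-1], frac, surfaced_frac)
}

#' Deposition profile container
#'
#' Fraction of the released methane dissolved per depth cell, plus the
#' fraction reaching the surface directly in the bubble. Fractions are
#' non-negative and sum to one with the surfaced fraction (enforced at
#' construction within 1e-9).
#'
#' @param cell_top,cell_bottom cell edges, m.
#' @param fraction fraction of released methane dissolved in each cell.
#' @param surfaced fraction surfacing in the bubble.
#' @return data frame of class `deposition_profile` with attribute
#'   `surfaced`.
#' @export
deposition_profile <- function(cell_top, cell_bottom, fraction, surfaced) {
  if (any(fraction < -1e-12) || surfaced < -1e-12)
    stop("deposition fractions must be non-negative", call. = FALSE)
  fraction <- pmax(fraction, 0)
  surfaced <- max(surfaced, 0)
  if (abs(sum(fraction) + surfaced - 1) > 1e-9)
    stop("deposition fractions and surfaced fraction must sum to 1", call. = FALSE)
  structure(data.frame(cell_top = cell_top, cell_bottom = cell_bottom,
                       fraction = fraction),
            surfaced = surfaced, class = c("deposition_profile", "data.frame"))
}

#' @export
print.deposition_profile <- function(x, ...) {
  cat(sprintf("<deposition_profile> %d cells to %g m; dissolved %.4f, surfaced %.4f\n",
              nrow(x), max(x$cell_bottom), sum(x$fraction), attr(x, "surfaced")))
  invisible(x)
}

#' Write / read a deposition profile as CSV
#'
#' The surfaced fraction is carried in a `surfaced` column (constant).
#'
#' @param dep a `deposition_profile`.
#' @param file CSV path.
#' @export
write_deposition_csv <- function(dep, file) {
  out <- data.frame(dep, surfaced = attr(dep, "surfaced"))
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_deposition_csv
#' @export
read_deposition_csv <- function(file) {
  d <- read.csv(file)
  deposition_profile(d$cell_top, d$cell_bottom, d$fraction, d$surfaced[1])
}
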