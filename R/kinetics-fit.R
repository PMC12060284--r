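#' Default prior box for the kinetics parameters
#'
#' Uniform priors: the half-life between 0.25 and 100 days; `Cb` and `Ctot`
#' non-negative, bounded above by ten times the largest observed activity so
#' the box is proper; a wide box on `ln_sigma`.
#'
#' @param data tracer dataset, used to scale the activity bounds.
#' @return named list of `c(lower, upper)` pairs in the order
#'   `t12_ref`, `Cb`, `Ctot`, `ln_sigma`.
#' @export
kinetics_priors <- function(data) {
  .check_tracer_data(data)
  amax <- max(abs(data$activity_normalized), 1)
  list(t12_ref = c(0.25, 100), Cb = c(0, 10 * amax), Ctot = c(0, 10 * amax),
       ln_sigma = c(-10, 5))
}

.par_names <- c("t12_ref", "Cb", "Ctot", "ln_sigma")

# effective incubation time: folds the Q10 scaling into t, and maps control
# samples to te = 0 (mean Cb) and pre-incubation samples to te = Inf (Ctot)
.effective_time <- function(data, Q10, T_ref) {
  te <- data$day * Q10^((data$temperature_C - T_ref) / 10)
  te[data$kind == "control"] <- 0
  te[data$kind == "pre"] <- Inf
  te
}

# validation-free negative log-likelihood; finite-difference gradients may
# probe slightly outside the box, so out-of-support points get a smooth
# penalty instead of an error
.neg_loglik_raw <- function(theta, te, y) {
  if (theta[1] <= 0 || theta[2] < 0 || theta[3] < 0)
    return(1e10 * (1 + sum(pmax(-theta[1:3], 0))))
  mu <- theta[3] - (theta[3] - theta[2]) * 2^(-te / theta[1])
  n <- length(y)
  n / 2 * log(2 * pi) + n * theta[4] + sum((y - mu)^2) / (2 * exp(2 * theta[4]))
}

#' Maximum-likelihood fit of the kinetics model
#'
#' Minimizes the negative log-likelihood over
#' `(t12_ref, Cb, Ctot, ln_sigma)` with box constraints matching the priors
#' (L-BFGS-B), and reports standard errors from the local curvature
#' (inverse observed information). Parameters may be held fixed via `fix`.
#'
#' @param data tracer dataset.
#' @param bounds prior box as from [kinetics_priors()].
#' @param start optional named start values.
#' @param fix named list of parameters to hold fixed.
#' @param Q10,T_ref fixed temperature-scaling constants.
#' @return object of class `kinetics_fit`: list with `params`
#'   ([kinetics_params()] at the optimum), `estimate`, `se`, `logLik`,
#'   `converged`, `identifiable` (`FALSE` when the fitted curve has no
#'   dynamic range or the information matrix is singular in the half-life),
#'   `message`.
#' @export
fit_mle <- function(data, bounds = kinetics_priors(data), start = NULL,
                    fix = list(), Q10 = 2, T_ref = 5) {
  .check_tracer_data(data)
  if (!all(names(fix) %in% .par_names)) stop("unknown parameter in fix", call. = FALSE)
  y <- data$activity_normalized
  default_start <- c(
    t12_ref = 10,
    Cb = max(min(y), 0),
    Ctot = max(y),
    ln_sigma = log(max(sd(y) / 2, 1e-3)))
  if (!is.null(start)) default_start[names(start)] <- unlist(start)
  start <- default_start
  lower <- vapply(bounds[.par_names], `[`, numeric(1), 1)
  upper <- vapply(bounds[.par_names], `[`, numeric(1), 2)
  start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)
  start["t12_ref"] <- max(start["t12_ref"], lower["t12_ref"])

  free <- setdiff(.par_names, names(fix))
  assemble <- function(th_free) {
    th <- setNames(numeric(4), .par_names)
    th[free] <- th_free
    for (nm in names(fix)) th[nm] <- fix[[nm]]
    th
  }
  te <- .effective_time(data, Q10, T_ref)
  obj <- function(th_free) .neg_loglik_raw(assemble(th_free), te, y)
  opt <- optim(start[free], obj, method = "L-BFGS-B",
               lower = lower[free], upper = upper[free],
               control = list(maxit = 1000, factr = 1e4), hessian = TRUE)
  if (opt$convergence != 0)
    warning("MLE optimizer did not converge: ", opt$message, call. = FALSE)

  se <- setNames(rep(NA_real_, 4), .par_names)
  cov_try <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(cov_try, "try-error")) {
    d <- diag(cov_try)
    se[free] <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  theta <- assemble(opt$par)
  # the half-life is unidentifiable when the fitted curve has no dynamic
  # range (Ctot ~ Cb) or the information matrix is singular in t12
  identifiable <- (theta["Ctot"] - theta["Cb"]) > 1e-8 &&
    (!("t12_ref" %in% free) || is.finite(se["t12_ref"]))
  structure(list(
    params = kinetics_params(theta[1], theta[2], theta[3], theta[4], Q10, T_ref),
    estimate = theta, se = se, logLik = -opt$value,
    converged = opt$convergence == 0, identifiable = unname(identifiable),
    message = opt$message),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit> maximum-likelihood estimate\n")
  print(data.frame(estimate = x$estimate, se = x$se))
  cat(sprintf("logLik = %.3f; converged: %s\n", x$logLik, x$converged))
  invisible(x)
}

# vectorized log-posterior over a matrix of walker positions (W x 4);
# rows outside the prior box get -Inf without a likelihood evaluation
.log_post_matrix <- function(theta, data, lower, upper, Q10, T_ref,
                             use_likelihood = TRUE) {
  W <- nrow(theta)
  lp <- numeric(W)
  inside <- rep(TRUE, W)
  for (j in 1:4) inside <- inside & theta[, j] >= lower[j] & theta[, j] <= upper[j]
  lp[!inside] <- -Inf
  if (!use_likelihood || !any(inside)) return(lp)

  te <- .effective_time(data, Q10, T_ref)
  y <- data$activity_normalized
  n <- length(y)

  th <- theta[inside, , drop = FALSE]
  decay <- 2^(-outer(1 / th[, 1], te))          # W_in x n
  mu <- th[, 3] - (th[, 3] - th[, 2]) * decay
  ss <- rowSums((matrix(y, nrow(th), n, byrow = TRUE) - mu)^2)
  s2 <- exp(2 * th[, 4])
  lp[inside] <- -n / 2 * log(2 * pi) - n * th[, 4] - ss / (2 * s2)
  lp
}

#' Posterior sampling by affine-invariant ensemble MCMC
#'
#' Samples the posterior implied by the Gaussian likelihood and the uniform
#' prior box with the Goodman & Weare stretch move (an ensemble of walkers,
#' each updated by stretching toward a randomly chosen partner). Walkers are
#' initialized in a small ball around the MLE (or spread over the prior when
#' the likelihood is switched off). Samples respect the prior support
#' exactly; results are reproducible for a fixed seed.
#'
#' @param data tracer dataset.
#' @param priors prior box, see [kinetics_priors()].
#' @param seed integer RNG seed.
#' @param n_walkers,n_steps,n_burn ensemble size, total steps, burn-in steps.
#' @param stretch_a stretch-move scale parameter (default 2).
#' @param Q10,T_ref fixed temperature-scaling constants.
#' @param use_likelihood set `FALSE` to sample the prior only (diagnostic).
#' @return object of class `kinetics_posterior`: list with `summary` (data
#'   frame: parameter, mle, stderr, p16, p50, p84), `chains` (array walker x
#'   step x parameter), `acceptance_fraction`, `ess` (effective sample sizes),
#'   `converged`, `mle` (the [fit_mle()] object or `NULL`).
#' @export
sample_posterior <- function(data, priors = kinetics_priors(data), seed = 1,
                             n_walkers = 32, n_steps = 5000, n_burn = 1000,
                             stretch_a = 2, Q10 = 2, T_ref = 5,
                             use_likelihood = TRUE) {
  .check_tracer_data(data)
  if (n_walkers < 8 || n_walkers %% 2 != 0)
    stop("n_walkers must be an even number >= 8", call. = FALSE)
  if (n_steps <= n_burn) stop("n_steps must exceed n_burn", call. = FALSE)
  lower <- vapply(priors[.par_names], `[`, numeric(1), 1)
  upper <- vapply(priors[.par_names], `[`, numeric(1), 2)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  mle <- NULL
  if (use_likelihood) {
    mle <- fit_mle(data, bounds = priors, Q10 = Q10, T_ref = T_ref)
    centre <- pmin(pmax(mle$estimate, lower + 1e-6), upper - 1e-6)
    scale <- pmax(abs(centre) * 0.01, 1e-4)
    X <- matrix(rnorm(n_walkers * 4), n_walkers, 4) * rep(scale, each = n_walkers) +
      rep(centre, each = n_walkers)
    X <- pmin(pmax(X, rep(lower + 1e-9, each = n_walkers)),
              rep(upper - 1e-9, each = n_walkers))
  } else {
    X <- sapply(1:4, function(j) runif(n_walkers, lower[j], upper[j]))
  }
  colnames(X) <- .par_names
  lp <- .log_post_matrix(X, data, lower, upper, Q10, T_ref, use_likelihood)

  chains <- array(NA_real_, c(n_walkers, n_steps, 4),
                  dimnames = list(NULL, NULL, .par_names))
  n_accept <- 0
  half <- n_walkers / 2
  idx1 <- seq_len(half)
  idx2 <- half + idx1
  d <- 4
  for (step in seq_len(n_steps)) {
    for (set in 1:2) {
      move <- if (set == 1) idx1 else idx2
      other <- if (set == 1) idx2 else idx1
      z <- ((stretch_a - 1) * runif(half) + 1)^2 / stretch_a
      partner <- other[sample.int(half, half, replace = TRUE)]
      Y <- X[partner, , drop = FALSE] + z * (X[move, , drop = FALSE] - X[partner, , drop = FALSE])
      lpY <- .log_post_matrix(Y, data, lower, upper, Q10, T_ref, use_likelihood)
      ln_accept <- (d - 1) * log(z) + lpY - lp[move]
      acc <- log(runif(half)) < ln_accept
      X[move[acc], ] <- Y[acc, , drop = FALSE]
      lp[move[acc]] <- lpY[acc]
      n_accept <- n_accept + sum(acc)
    }
    chains[, step, ] <- X
  }
  accept_frac <- n_accept / (n_steps * n_walkers)

  post <- chains[, (n_burn + 1):n_steps, , drop = FALSE]
  flat <- matrix(post, ncol = 4, dimnames = list(NULL, .par_names))
  qs <- apply(flat, 2, quantile, probs = c(0.16, 0.5, 0.84), names = FALSE)
  summary <- data.frame(
    parameter = .par_names,
    mle = if (is.null(mle)) NA_real_ else unname(mle$estimate),
    stderr = if (is.null(mle)) NA_real_ else unname(mle$se),
    p16 = qs[1, ], p50 = qs[2, ], p84 = qs[3, ], row.names = NULL)

  ess <- vapply(1:4, function(j) .ensemble_ess(post[, , j]), numeric(1))
  names(ess) <- .par_names
  converged <- accept_frac > 0.05 && accept_frac < 0.95 && all(ess > 50)
  if (!converged)
    warning(sprintf(
      "posterior sampling convergence diagnostics failed (acceptance %.2f, min ESS %.0f)",
      accept_frac, min(ess)), call. = FALSE)

  structure(list(summary = summary, chains = chains,
                 acceptance_fraction = accept_frac, ess = ess,
                 converged = converged, mle = mle,
                 n_burn = n_burn, seed = seed),
            class = "kinetics_posterior")
}

# effective sample size from the integrated autocorrelation time of the
# walker-averaged chain (Goodman & Weare's recommended estimator)
.ensemble_ess <- function(walker_by_step) {
  m <- colMeans(walker_by_step)
  n <- length(m)
  m <- m - mean(m)
  if (sd(m) == 0) return(nrow(walker_by_step) * n)
  ac <- stats::acf(m, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  # sum positive-leading pairs (initial positive sequence heuristic)
  tau <- 1
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    tau <- tau + 2 * ac[k]
  }
  nrow(walker_by_step) * n / tau
}

#' @export
print.kinetics_posterior <- function(x, ...) {
  cat("<kinetics_posterior> affine-invariant ensemble MCMC\n")
  print(x$summary, digits = 4)
  cat(sprintf("acceptance fraction %.2f; min ESS %.0f\n",
              x$acceptance_fraction, min(x$ess)))
  invisible(x)
}

#' Write posterior summary and chains to plain-text files
#'
#' The summary goes to `summary.csv` (parameter, mle, stderr, p16, p50, p84)
#' and the chains to `chains.csv` in long format (walker, step, parameter,
#' value).
#'
#' @param posterior a `kinetics_posterior`.
#' @param path output directory.
#' @export
write_posterior <- function(posterior, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(posterior$summary, file.path(path, "summary.csv"), row.names = FALSE)
  dims <- dim(posterior$chains)
  long <- data.frame(
    walker = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    step = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    parameter = rep(.par_names, each = dims[1] * dims[2]),
    value = as.vector(posterior$chains))
  write.csv(long, file.path(path, "chains.csv"), row.names = FALSE)
  invisible(path)
}
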