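#' Noise specification for partial-stochastic simulation
#'
#' The network ODEs are extended with two perturbation sources: a Gaussian
#' perturbation of each initial-condition component (sd `ic_sigma`,
#' truncated at 0), reflecting biological variability in starting states,
#' and an additive per-step fluctuation `sigma * sqrt(dt) * eta` with
#' standard-normal `eta`, mimicking continuous molecular noise
#' (Euler-Maruyama update).
#'
#' The fixed step must satisfy `dt < 0.1 / max(kd)` for explicit-Euler
#' stability; this is checked at construction against the baseline
#' degradation constants.
#'
#' @param sigma Amplitude of the per-step random perturbation (a.u.),
#'   >= 0. The default 0.001 keeps the ensemble in the regime where the
#'   stochastic mean stays close to the deterministic limit cycle and the
#'   trajectory envelope stays narrow relative to the oscillation
#'   amplitude; larger values progressively dephase the ensemble (additive
#'   noise on a limit cycle diffuses the oscillation phase, and the mean of
#'   dephased cycles flattens).
#' @param dt Fixed Euler-Maruyama time step (a.u. time). Default 0.01.
#' @param ic_sigma Standard deviation of the initial-condition perturbation
#'   (a.u.), >= 0. Default 0.05.
#' @param n_traj Ensemble size (default 1000).
#' @param seed Master RNG seed; per-trajectory substreams are derived from
#'   it, so ensembles are reproducible and order-independent.
#' @param reflect Reflect negative excursions at zero (default FALSE; the
#'   fraction of negative samples is reported in the summary).
#' @param params Optional [network_params()] used for the dt stability check.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.001, dt = 0.01, ic_sigma = 0.05,
                       n_traj = 1000L, seed = 1L, reflect = FALSE,
                       params = NULL) {
  if (sigma < 0 || ic_sigma < 0) stop("sigma and ic_sigma must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_traj < 1L) stop("n_traj must be >= 1")
  if (!is.null(params)) {
    kdmax <- max(params$kdNotch, params$kdWntSC, params$kdWntTA,
                 params$kdYAP)
    if (dt >= 0.1 / kdmax)
      stop("dt too large for explicit-Euler stability: need dt < ",
           format(0.1 / kdmax))
  }
  structure(list(sigma = sigma, dt = dt, ic_sigma = ic_sigma,
                 n_traj = as.integer(n_traj), seed = as.integer(seed),
                 reflect = isTRUE(reflect)),
            class = "noise_spec")
}

#' One Euler-Maruyama step
#'
#' `state + network_rhs(state) * dt + sigma * sqrt(dt) * eta`, componentwise.
#' With `sigma = 0` this is one explicit-Euler step.
#'
#' @param state Activity state (length-4 numeric).
#' @param params A [network_params()].
#' @param spec A [noise_spec()].
#' @param eta Four standard-normal draws (default: drawn from the session
#'   RNG).
#' @return The advanced state (named numeric).
#' @export
em_step <- function(state, params, spec, eta = stats::rnorm(4L)) {
  s <- as_state(state)
  out <- s + network_rhs(s, params) * spec$dt +
    spec$sigma * sqrt(spec$dt) * eta
  if (spec$reflect) out <- abs(out)
  as_state(out)
}

#' Simulate a stochastic ensemble of network trajectories
#'
#' Runs `n_traj` Euler-Maruyama trajectories with independently perturbed
#' initial conditions and independent per-step noise, each under its own
#' RNG substream derived from the master seed. Returns per-time mean and
#' min/max envelope across trajectories together with the deterministic
#' reference trajectory (adaptive Runge-Kutta from the unperturbed start).
#'
#' Trajectories that diverge to non-finite values are excluded and counted;
#' more than 1 percent exclusions is an error.
#'
#' @param params A [network_params()].
#' @param base_ic Unperturbed initial [activity_state()].
#' @param spec A [noise_spec()].
#' @param t_end Simulation horizon (a.u.), > 0.
#' @param record_dt Spacing of the recorded grid (a.u.; default 1). Must be
#'   a multiple of `spec$dt`.
#' @return An object of class `ensemble_summary`: list with `times`, and
#'   4-column matrices `mean`, `env_min`, `env_max`, `deterministic`, plus
#'   `n_traj`, `n_excluded`, `negative_fraction` and the spec.
#' @export
simulate_ensemble <- function(params, base_ic = activity_state(), spec,
                              t_end, record_dt = 1) {
  stopifnot(inherits(spec, "noise_spec"), t_end > 0)
  y0 <- as_state(base_ic)
  record_every <- round(record_dt / spec$dt)
  if (abs(record_every * spec$dt - record_dt) > 1e-9)
    stop("record_dt must be a multiple of spec$dt")
  nsteps <- ceiling(t_end / spec$dt)
  nsteps <- (nsteps %/% record_every) * record_every
  times <- seq(0, by = record_dt, length.out = nsteps / record_every + 1)

  pvec <- unlist(unclass(params))[rate_symbols()]
  traj_seeds <- withr_seed(spec$seed,
                           sample.int(.Machine$integer.max, spec$n_traj))
  nrec <- length(times)
  sum_mat <- matrix(0, nrec, 4L)
  min_mat <- matrix(Inf, nrec, 4L)
  max_mat <- matrix(-Inf, nrec, 4L)
  n_neg <- 0; n_samp <- 0
  excluded <- 0L
  for (i in seq_len(spec$n_traj)) {
    m <- withr_seed(traj_seeds[i], {
      ic <- pmax(0, y0 + stats::rnorm(4L, sd = spec$ic_sigma))
      em_trajectory_cpp(ic, pvec, params$n, spec$sigma, spec$dt,
                        nsteps, record_every, spec$reflect)
    })
    if (anyNA(m)) { excluded <- excluded + 1L; next }
    sum_mat <- sum_mat + m
    min_mat <- pmin(min_mat, m)
    max_mat <- pmax(max_mat, m)
    n_neg <- n_neg + sum(m < 0)
    n_samp <- n_samp + length(m)
  }
  kept <- spec$n_traj - excluded
  if (excluded > 0.01 * spec$n_traj)
    stop(excluded, " of ", spec$n_traj, " trajectories diverged")
  if (kept == 0L) stop("all trajectories diverged")

  det <- integrate_network(params, y0, t_end = max(times), dt = record_dt,
                           method = "lsoda", rtol = 1e-10, atol = 1e-12)
  det_mat <- as.matrix(det[state_names()])

  mean_mat <- sum_mat / kept
  colnames(mean_mat) <- colnames(min_mat) <- colnames(max_mat) <-
    state_names()
  structure(list(times = times, mean = mean_mat, env_min = min_mat,
                 env_max = max_mat, deterministic = det_mat,
                 n_traj = kept, n_excluded = excluded,
                 negative_fraction = n_neg / max(n_samp, 1L),
                 spec = spec, params = params, base_ic = y0),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Stochastic ensemble: %d trajectories (%d excluded), t in [0, %g]\n",
    x$n_traj, x$n_excluded, max(x$times)))
  cat(sprintf("  sigma=%g ic_sigma=%g dt=%g seed=%d\n", x$spec$sigma,
              x$spec$ic_sigma, x$spec$dt, x$spec$seed))
  if (x$negative_fraction > 0)
    cat(sprintf("  negative samples: %.3g%%\n", 100 * x$negative_fraction))
  rmse <- sqrt(colMeans((x$mean - x$deterministic)^2))
  cat("  RMSE(mean, deterministic):",
      paste(sprintf("%s=%.4g", state_names(), rmse), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.ensemble_summary <- function(x, var = "A_Notch", ...) {
  j <- match(var, state_names())
  graphics::plot(x$times, x$mean[, j], type = "n",
                 ylim = range(x$env_min[, j], x$env_max[, j]),
                 xlab = "time (a.u.)", ylab = paste(var, "(a.u.)"), ...)
  graphics::polygon(c(x$times, rev(x$times)),
                    c(x$env_min[, j], rev(x$env_max[, j])),
                    col = "grey85", border = NA)
  graphics::lines(x$times, x$mean[, j], lwd = 1.5)
  graphics::lines(x$times, x$deterministic[, j], lty = 2)
  invisible(x)
}

#' Deviation of the stochastic mean from the deterministic path
#'
#' Per-variable root-mean-square error between the ensemble mean and the
#' deterministic reference, envelope-width statistics, and the location of
#' the largest mean deviation relative to the nearest deterministic
#' extremum (in absolute time and as a fraction of the deterministic
#' period).
#'
#' @param summary An [simulate_ensemble()] result.
#' @param burn_in_fraction Fraction of the horizon skipped before locating
#'   the largest deviation (default 0.25, past initial-condition scatter).
#' @return A data.frame with one row per variable: `rmse`,
#'   `envelope_width_mean`, `envelope_width_max`, `t_max_dev`,
#'   `dist_to_extremum`, `dist_frac_period`.
#' @export
deviation_report <- function(summary, burn_in_fraction = 0.25) {
  x <- summary
  det_traj <- data.frame(time = x$times, x$deterministic)
  names(det_traj) <- c("time", state_names())
  met <- oscillation_metrics(det_traj, burn_in_fraction = burn_in_fraction)
  sel <- x$times >= burn_in_fraction * max(x$times)
  rows <- lapply(state_names(), function(v) {
    j <- match(v, state_names())
    dev <- abs(x$mean[, j] - x$deterministic[, j])
    width <- x$env_max[, j] - x$env_min[, j]
    i_max <- which(sel)[which.max(dev[sel])]
    t_max <- x$times[i_max]
    ext <- c(met$variables[[v]]$peak_times, met$variables[[v]]$trough_times)
    dist <- if (length(ext)) min(abs(t_max - ext)) else NA_real_
    per <- met$variables[[v]]$period
    data.frame(variable = v, rmse = sqrt(mean((dev)^2)),
               envelope_width_mean = mean(width),
               envelope_width_max = max(width),
               t_max_dev = t_max, dist_to_extremum = dist,
               dist_frac_period = if (is.finite(per)) dist / per
                                  else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write an ensemble summary as tidy CSV
#'
#' Columns `time, variable, mean, env_min, env_max, deterministic`.
#'
#' @param summary An `ensemble_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(summary, path) {
  rows <- lapply(state_names(), function(v) {
    j <- match(v, state_names())
    data.frame(time = summary$times, variable = v,
               mean = summary$mean[, j], env_min = summary$env_min[, j],
               env_max = summary$env_max[, j],
               deterministic = summary$deterministic[, j])
  })
  write_tidy_csv(do.call(rbind, rows), path)
}
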