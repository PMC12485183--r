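#' Oscillatory range of one parameter
#'
#' The interval of a rate constant over which the network exhibits limit
#' cycle oscillations, with all other parameters held at the baseline in
#' `params`. Two methods are available:
#'
#' * `"hopf_pair"` (default): the interval between the two Hopf points on
#'   the continued equilibrium branch.
#' * `"amplitude_scan"`: direct simulation on a coarse grid over the
#'   bracket, with bisection on the sustained-oscillation flag at each
#'   boundary. This also covers ranges whose cycles are born subcritically
#'   (the cycle persists beyond the Hopf point, up to a cycle fold) or whose
#'   lower end is the physical boundary 0.
#'
#' With `cross_validate = TRUE` the Hopf interval is checked by simulation:
#' sustained at the midpoint, decaying just outside each end.
#'
#' @param params Baseline [network_params()].
#' @param vary Rate-constant name.
#' @param bracket Search interval.
#' @param method `"hopf_pair"` or `"amplitude_scan"`.
#' @param cross_validate Simulate to confirm the Hopf interval (default
#'   FALSE; the acceptance analyses enable it selectively).
#' @param sim_t_end,sim_dt Horizon and output spacing of validation /
#'   scan simulations.
#' @return An object of class `oscillatory_range`: list with `vary`, `low`,
#'   `high`, `method`, and (for the Hopf route) the underlying branch.
#' @export
oscillatory_range <- function(params, vary, bracket,
                              method = c("hopf_pair", "amplitude_scan"),
                              cross_validate = FALSE,
                              sim_t_end = 8000, sim_dt = 2) {
  method <- match.arg(method)
  if (method == "hopf_pair") {
    br <- continue_equilibria(params, vary, bracket)
    hp <- hopf_points(br)
    hp <- hp[hp$param >= min(bracket) & hp$param <= max(bracket), ,
             drop = FALSE]
    if (nrow(hp) != 2L)
      stop("expected exactly 2 Hopf points in the bracket for '", vary,
           "', found ", nrow(hp), call. = FALSE)
    low <- min(hp$param); high <- max(hp$param)
    if (cross_validate) {
      pad <- pmax(0.02 * c(low, high), 0.05 * (high - low))
      a_mid <- notch_amplitude_at(params, vary, (low + high) / 2,
                                  sim_t_end, sim_dt)
      a_lo <- notch_amplitude_at(params, vary, low - pad[1L],
                                 sim_t_end, sim_dt)
      a_hi <- notch_amplitude_at(params, vary, high + pad[2L],
                                 sim_t_end, sim_dt)
      if (a_mid < 1e-3 || a_lo > 0.1 * a_mid || a_hi > 0.1 * a_mid)
        warning("simulation cross-check disagrees with the Hopf interval ",
                "for '", vary, "' (subcritical birth of the cycle can ",
                "extend oscillations beyond a Hopf point)")
    }
    res <- list(vary = vary, low = low, high = high, method = method,
                branch = br)
  } else {
    res <- amplitude_scan_range(params, vary, bracket, sim_t_end, sim_dt)
  }
  structure(res, class = "oscillatory_range")
}

#' @export
print.oscillatory_range <- function(x, ...) {
  cat(sprintf("oscillatory range of %s: [%.6g, %.6g] (%s)\n",
              x$vary, x$low, x$high, x$method))
  invisible(x)
}

# sustained-oscillation flag of a long simulation at one parameter value
sustained_at <- function(params, vary, value, t_end = 8000, dt = 2) {
  p <- params
  p[[vary]] <- max(value, 0)
  traj <- integrate_network(p, activity_state(), t_end = t_end, dt = dt,
                            method = "lsoda", rtol = 1e-9, atol = 1e-11)
  m <- oscillation_metrics(traj, burn_in_fraction = 0.6)
  isTRUE(m$variables$A_Notch$sustained)
}

# post-burn-in Notch amplitude of a long simulation at one parameter value
notch_amplitude_at <- function(params, vary, value, t_end = 8000, dt = 2) {
  p <- params
  p[[vary]] <- max(value, 0)
  traj <- integrate_network(p, activity_state(), t_end = t_end, dt = dt,
                            method = "lsoda", rtol = 1e-9, atol = 1e-11)
  m <- oscillation_metrics(traj, burn_in_fraction = 0.6)
  m$variables$A_Notch$amplitude
}

# coarse grid + boundary bisection on the sustained flag
amplitude_scan_range <- function(params, vary, bracket, t_end, dt,
                                 n_grid = 13L, tol = 1e-3) {
  lo <- min(bracket); hi <- max(bracket)
  grid <- seq(lo, hi, length.out = n_grid)
  osc <- vapply(grid, function(v) sustained_at(params, vary, v, t_end, dt),
                logical(1))
  if (!any(osc))
    stop("no sustained oscillation found in the bracket for '", vary, "'")
  i1 <- which(osc)[1L]; i2 <- rev(which(osc))[1L]
  low <- if (i1 == 1L) lo else
    bisect_flag(params, vary, grid[i1 - 1L], grid[i1], t_end, dt, tol)
  high <- if (i2 == n_grid) hi else
    bisect_flag(params, vary, grid[i2 + 1L], grid[i2], t_end, dt, tol)
  list(vary = vary, low = low, high = high, method = "amplitude_scan",
       grid = data.frame(value = grid, sustained = osc))
}

# v_no does not oscillate, v_yes does; returns the boundary
bisect_flag <- function(params, vary, v_no, v_yes, t_end, dt, tol) {
  while (abs(v_yes - v_no) > tol) {
    mid <- (v_no + v_yes) / 2
    if (sustained_at(params, vary, mid, t_end, dt)) v_yes <- mid
    else v_no <- mid
  }
  (v_no + v_yes) / 2
}

# default scan brackets around the oscillatory baseline, one per rate
default_scan_brackets <- function() {
  list(kNotch = c(0.8, 1.3), kWntSC = c(1.2, 1.7), kWntTA = c(0.3, 1.2),
       kYAP = c(0.12, 0.22),
       kdNotch = c(0.15, 0.25), kdWntSC = c(0.15, 0.25),
       kdWntTA = c(0.15, 0.45), kdYAP = c(0.015, 0.03),
       kPNotch = c(0.03, 0.08), kPWntSC = c(0.05, 0.2),
       kPWntTA = c(0, 0.2), kPYAP = c(0.05, 0.15))
}

#' Scan the oscillatory range of each rate constant
#'
#' One-at-a-time scan: for each requested symbol the oscillatory interval is
#' computed with all other parameters at the baseline. The Hopf-pair method
#' is tried first; when the bracket does not contain a Hopf pair (as happens
#' when the cycle is born subcritically at one end, or oscillations extend
#' to the physical boundary 0), the amplitude-scan method supplies the
#' interval and the `method` column records it.
#'
#' @param params Baseline [network_params()].
#' @param symbols Character vector of rate names (default: all 12).
#' @param brackets Named list of search intervals (defaults chosen around
#'   the oscillatory baseline).
#' @param cross_validate Passed to [oscillatory_range()].
#' @return A data.frame with columns `parameter`, `low`, `high`, `method`,
#'   `error` (NA on success; per-symbol failures do not stop the scan).
#' @export
scan_table <- function(params = network_params(),
                       symbols = rate_symbols(),
                       brackets = default_scan_brackets(),
                       cross_validate = FALSE) {
  bad <- setdiff(symbols, rate_symbols())
  if (length(bad)) stop("unknown rate symbol(s): ", paste(bad, collapse = ", "))
  if (!length(symbols))
    return(data.frame(parameter = character(), low = numeric(),
                      high = numeric(), method = character(),
                      error = character()))
  rows <- lapply(symbols, function(sym) {
    bracket <- brackets[[sym]]
    if (is.null(bracket))
      return(data.frame(parameter = sym, low = NA_real_, high = NA_real_,
                        method = NA_character_,
                        error = "no bracket supplied"))
    r <- tryCatch(
      oscillatory_range(params, sym, bracket, method = "hopf_pair",
                        cross_validate = cross_validate),
      error = function(e) e)
    if (inherits(r, "error")) {
      r <- tryCatch(
        oscillatory_range(params, sym, bracket, method = "amplitude_scan"),
        error = function(e) e)
    }
    if (inherits(r, "error"))
      return(data.frame(parameter = sym, low = NA_real_, high = NA_real_,
                        method = NA_character_,
                        error = conditionMessage(r)))
    data.frame(parameter = sym, low = r$low, high = r$high,
               method = r$method, error = NA_character_)
  })
  do.call(rbind, rows)
}

#' Quasi-static hysteresis sweep
#'
#' Steps the varied parameter monotonically through the bracket; at each
#' step the system is integrated to steady state starting from the previous
#' settled state. In a bistable window the up- and down-sweeps settle on
#' different branches, and the jump locations bracket the fold points.
#'
#' @param params Baseline [network_params()].
#' @param vary Rate-constant name.
#' @param bracket Sweep interval.
#' @param direction `"up"` (left to right) or `"down"`.
#' @param n_steps Number of sweep points.
#' @param settle_t Integration horizon per chunk; chunks repeat until
#'   `max |rhs| < settle_tol` or `max_chunks` is hit (then the point is
#'   flagged unconverged, e.g. in an oscillatory regime).
#' @param settle_tol Steady-state residual tolerance.
#' @param max_chunks Maximum settle chunks per step.
#' @param init Starting state for the first step.
#' @return A data.frame with `param`, the settled state columns, and
#'   `converged`.
#' @export
hysteresis_sweep <- function(params, vary, bracket,
                             direction = c("up", "down"), n_steps = 41L,
                             settle_t = 1500, settle_tol = 1e-8,
                             max_chunks = 4L, init = activity_state()) {
  direction <- match.arg(direction)
  vals <- seq(min(bracket), max(bracket), length.out = n_steps)
  if (direction == "down") vals <- rev(vals)
  y <- as_state(init)
  rows <- vector("list", n_steps)
  for (i in seq_along(vals)) {
    p <- params
    p[[vary]] <- vals[i]
    conv <- FALSE
    for (ch in seq_len(max_chunks)) {
      traj <- integrate_network(p, y, t_end = settle_t, dt = settle_t / 200,
                                method = "lsoda", rtol = 1e-10, atol = 1e-12)
      y <- as_state(as.numeric(traj[nrow(traj), state_names()]))
      if (max(abs(network_rhs(y, p))) < settle_tol) { conv <- TRUE; break }
    }
    # polish onto the equilibrium when close
    if (conv) {
      eq <- newton_equilibrium(y, p)
      if (eq$converged) y <- as_state(pmax(eq$x, 0))
    }
    rows[[i]] <- data.frame(param = vals[i], t(y), converged = conv)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("param", state_names(), "converged")
  attr(out, "direction") <- direction
  attr(out, "vary") <- vary
  out
}

#' Jump locations of a hysteresis sweep
#'
#' The sweep parameter interval over which the settled Notch activity jumps
#' by more than `jump_min` between consecutive steps.
#'
#' @param sweep Result of [hysteresis_sweep()].
#' @param jump_min Minimum jump in `A_Notch` (a.u.) to count (default 0.5).
#' @return A data.frame with one row per jump: `from`, `to` (parameter
#'   values bracketing the jump) and `delta` (signed change in `A_Notch`).
#' @export
sweep_jumps <- function(sweep, jump_min = 0.5) {
  dx <- diff(sweep$A_Notch)
  idx <- which(abs(dx) > jump_min)
  data.frame(from = sweep$param[idx], to = sweep$param[idx + 1L],
             delta = dx[idx])
}
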