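#' Oscillation metrics of a simulated trajectory
#'
#' Detects peaks and troughs of each activity after a burn-in window, and
#' summarizes period, amplitude and phase structure. Extrema are local
#' extrema passing a prominence filter (a fraction of the variable's
#' post-burn-in range); the period is the mean inter-peak interval.
#'
#' A variable is flagged `sustained` when, in the final analysis window,
#' (i) its amplitude exceeds `amplitude_threshold`, (ii) successive
#' inter-peak intervals vary by less than 5 percent relative, and (iii) the
#' amplitude in the last quarter of the window is at least half of that in
#' the preceding quarter, which excludes slowly decaying spirals.
#'
#' @param traj An `nwy_trajectory` from [integrate_network()] (any data.frame
#'   with a `time` column and the four activity columns works).
#' @param burn_in_fraction Fraction of the horizon discarded before analysis
#'   (default 0.5; limit-cycle attraction makes metrics insensitive to the
#'   initial state after this).
#' @param prominence_frac Prominence filter as a fraction of the variable's
#'   post-burn-in range (default 0.01).
#' @param amplitude_threshold Minimum peak-to-trough amplitude (a.u.) for a
#'   variable to count as oscillating (default 1e-3).
#' @return An object of class `oscillation_metrics`: per-variable list with
#'   `period`, `amplitude`, `sustained`, `peak_times`, `trough_times`, plus
#'   the common period estimate and pairwise `phase_offsets` (peak-time
#'   differences normalized by the period, in \[0, 1)).
#' @export
oscillation_metrics <- function(traj, burn_in_fraction = 0.5,
                                prominence_frac = 0.01,
                                amplitude_threshold = 1e-3) {
  df <- as.data.frame(traj)
  t0 <- min(df$time) + burn_in_fraction * (max(df$time) - min(df$time))
  w <- df[df$time >= t0, , drop = FALSE]
  vars <- intersect(state_names(), names(w))
  per_var <- lapply(vars, function(v)
    variable_metrics(w$time, w[[v]], prominence_frac, amplitude_threshold))
  names(per_var) <- vars
  periods <- vapply(per_var, function(m) m$period, numeric(1))
  common <- if (all(is.finite(periods))) mean(periods) else NA_real_
  offsets <- phase_offset_matrix(per_var, common)
  structure(list(variables = per_var, period = common,
                 phase_offsets = offsets,
                 sustained = all(vapply(per_var, `[[`, logical(1),
                                        "sustained")),
                 window = range(w$time)),
            class = "oscillation_metrics")
}

# peak/trough detection for one signal; returns metrics for that variable
variable_metrics <- function(time, x, prominence_frac, amplitude_threshold) {
  rng <- diff(range(x))
  prom <- prominence_frac * rng
  pk <- local_extrema(time, x, prom, maxima = TRUE)
  tr <- local_extrema(time, x, prom, maxima = FALSE)
  amplitude <- rng
  period <- NA_real_
  regular <- FALSE
  if (length(pk$time) >= 2L) {
    iv <- diff(pk$time)
    period <- mean(iv)
    regular <- length(iv) >= 1L && max(abs(iv - period)) / period < 0.05
  }
  # amplitude trend over the last two quarter-windows (decay guard)
  qs <- seq(min(time), max(time), length.out = 5L)
  a3 <- amp_in(time, x, qs[3L], qs[4L])
  a4 <- amp_in(time, x, qs[4L], qs[5L])
  non_decaying <- a3 <= amplitude_threshold || a4 >= 0.5 * a3
  sustained <- is.finite(period) && amplitude > amplitude_threshold &&
    regular && non_decaying
  list(period = period, amplitude = amplitude, sustained = sustained,
       peak_times = pk$time, peak_values = pk$value,
       trough_times = tr$time, trough_values = tr$value)
}

amp_in <- function(time, x, a, b) {
  sel <- time >= a & time <= b
  if (!any(sel)) return(0)
  diff(range(x[sel]))
}

# strict local extrema with a prominence filter; ties broken by earliest time
local_extrema <- function(time, x, prominence, maxima = TRUE) {
  s <- if (maxima) x else -x
  d <- diff(s)
  idx <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (length(idx)) {
    keep <- vapply(idx, function(i) {
      lo <- max(1L, i - 1L)
      # prominence relative to the lower of the two neighboring troughs
      left <- min(s[1L:i]); right <- min(s[i:length(s)])
      s[i] - max(left, right) >= prominence
    }, logical(1))
    idx <- idx[keep]
  }
  list(time = time[idx], value = x[idx])
}

phase_offset_matrix <- function(per_var, period) {
  vars <- names(per_var)
  m <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  if (!is.finite(period)) return(m)
  for (a in vars) for (b in vars) {
    ta <- per_var[[a]]$peak_times
    tb <- per_var[[b]]$peak_times
    if (!length(ta) || !length(tb)) next
    # mean cyclic offset of b's peaks relative to a's nearest earlier peak
    off <- vapply(tb, function(t) {
      d <- (t - ta) %% period
      min(d)
    }, numeric(1))
    m[a, b] <- (mean(off) / period) %% 1
  }
  m
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat("Oscillation metrics (window",
      sprintf("[%.4g, %.4g]", x$window[1L], x$window[2L]), ")\n")
  for (v in names(x$variables)) {
    m <- x$variables[[v]]
    cat(sprintf("  %-8s period=%-8.4g amplitude=%-8.4g sustained=%s\n",
                v, m$period, m$amplitude, m$sustained))
  }
  cat("  common period:", format(x$period, digits = 6),
      " all sustained:", x$sustained, "\n")
  invisible(x)
}

#' Qualitative phase relations between oscillating activities
#'
#' Classifies each variable pair: `aligned` when the peaks of `var_a` fall
#' within `align_tol` of a cycle (0 or 1) of the peaks of `var_b`, and
#' `anti_phase` when the peaks of `var_a` fall within `align_tol` of the
#' *troughs* of `var_b`. Anti-phase is deliberately peak-to-trough rather
#' than peak-to-peak at half a cycle: relaxation-type cycles are asymmetric,
#' so a peak of one variable coinciding with the trough of another (the
#' biologically meaningful opposition) need not put their peaks half a
#' cycle apart. Requires sustained oscillation.
#'
#' @param metrics An [oscillation_metrics()] result with `sustained = TRUE`.
#' @param align_tol Classification half-width in cycles (default 0.15).
#' @return A data.frame with columns `var_a`, `var_b`, `peak_offset`
#'   (peak-to-peak, cycles), `trough_offset` (peak of a to trough of b,
#'   cycles) and `relation`.
#' @export
phase_relations <- function(metrics, align_tol = 0.15) {
  if (!isTRUE(metrics$sustained))
    stop("phase relations require sustained oscillation in all variables")
  vars <- names(metrics$variables)
  period <- metrics$period
  out <- expand.grid(var_a = vars, var_b = vars, stringsAsFactors = FALSE)
  cyc <- function(a_times, b_times) {
    if (!length(a_times) || !length(b_times)) return(NA_real_)
    off <- vapply(a_times, function(t) min((t - b_times) %% period),
                  numeric(1))
    (mean(off) / period) %% 1
  }
  out$peak_offset <- mapply(function(a, b)
    cyc(metrics$variables[[a]]$peak_times,
        metrics$variables[[b]]$peak_times), out$var_a, out$var_b)
  out$trough_offset <- mapply(function(a, b)
    cyc(metrics$variables[[a]]$peak_times,
        metrics$variables[[b]]$trough_times), out$var_a, out$var_b)
  near0 <- function(x) pmin(x %% 1, 1 - x %% 1)
  out$relation <- ifelse(near0(out$peak_offset) <= align_tol, "aligned",
                         ifelse(near0(out$trough_offset) <= align_tol,
                                "anti_phase", "intermediate"))
  out
}
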