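#' Parameters of the TDC population model
#'
#' The basal-layer population model for terminally differentiated cells
#' (TDCs) produced from transit amplifying cells by Delta-Notch contact with
#' an epidermal stem cell:
#' dC/dt = (k1 * d / (k2 + C) - kd1) * C.
#' The Michaelis-Menten-type production term treats the SC surface Delta/DLL
#' concentration `d` as the enzyme; the TAC and TDC densities are equal by
#' the homeostasis argument, so a single density C appears.
#'
#' Only the ratio k1/kd1 and k2 are identifiable from the steady-state
#' relation; [tdc_params_ratio()] constructs a set from that ratio with
#' kd1 fixed at 1.
#'
#' @param k1 Rate constant of TDC generation via Notch activation by the SC
#'   (1/time per a.u. Delta), > 0.
#' @param k2 Fold decrease in TDC production due to Notch-independent
#'   apoptosis (cell-density a.u.), > 0.
#' @param kd1 Rate constant of TDC movement to the suprabasal layers
#'   (1/time), > 0.
#' @param d Delta/DLL concentration on the SC surface (a.u.), >= 0.
#' @return An object of class `tdc_params`.
#' @examples
#' p <- tdc_params_ratio(ratio = 0.01, k2 = 0.05, d = 10)
#' critical_delta(p)   # 5
#' @export
tdc_params <- function(k1, k2, kd1, d = 0) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(kd1), is.numeric(d))
  if (k1 <= 0 || k2 <= 0 || kd1 <= 0) stop("k1, k2 and kd1 must be > 0")
  if (d < 0) stop("Delta level 'd' must be >= 0")
  structure(list(k1 = k1, k2 = k2, kd1 = kd1, d = d), class = "tdc_params")
}

#' @rdname tdc_params
#' @param ratio The identifiable ratio k1/kd1.
#' @export
tdc_params_ratio <- function(ratio, k2, kd1 = 1, d = 0) {
  tdc_params(k1 = ratio * kd1, k2 = k2, kd1 = kd1, d = d)
}

#' @export
print.tdc_params <- function(x, ...) {
  cat(sprintf(
    "TDC population model: k1=%g, k2=%g, kd1=%g (k1/kd1=%g), d=%g\n",
    x$k1, x$k2, x$kd1, x$k1 / x$kd1, x$d))
  cat(sprintf("  critical Delta d_cr = %g\n", critical_delta(x)))
  invisible(x)
}

#' Rate of change of the TDC number density
#'
#' @param C Non-negative TDC number density (a.u.).
#' @param p A [tdc_params()] object.
#' @return dC/dt = (k1*d/(k2 + C) - kd1) * C.
#' @export
tdc_rhs <- function(C, p) {
  if (any(C < 0)) stop("TDC density must be >= 0")
  (p$k1 * p$d / (p$k2 + C) - p$kd1) * C
}

#' Critical Delta level for epidermal stemness
#'
#' The Delta/DLL concentration below which the positive TDC steady state
#' vanishes: d_cr = k2 * kd1 / k1 (the rate of TDC loss over the rate of TDC
#' generation). A basal keratinocyte expressing Delta above d_cr can induce
#' terminal differentiation in a contacting TAC and is thereby a stem cell.
#'
#' @param p A [tdc_params()] object.
#' @return d_cr (a.u.).
#' @export
critical_delta <- function(p) p$k2 * p$kd1 / p$k1

#' Steady states of the TDC density and their stability
#'
#' Solves dC/dt = 0 analytically. C = 0 is always a steady state. For
#' d > d_cr there is in addition the positive state C = k1*d/kd1 - k2, which
#' is stable while C = 0 is unstable (sign of the linearization
#' k1*d/k2 - kd1 at 0, and of the perturbation response at the positive
#' state). For d < d_cr only C = 0 exists and it is stable. At d = d_cr the
#' two merge into a single state at 0 that is semistable in the strict sense
#' (the flow is non-positive for C >= 0, so it attracts from the right);
#' it is reported as `"stable"` with the internal label retained in
#' `$semistable_at_zero`.
#'
#' @param p A [tdc_params()] object.
#' @param tol Tolerance for classifying d at the critical value.
#' @return An object of class `tdc_steady_states`: list with `states`
#'   (data.frame of `c_tdc` and `stability`), `d_cr` and `regime`.
#' @export
tdc_steady_states <- function(p, tol = 1e-12) {
  dcr <- critical_delta(p)
  pos <- p$k1 * p$d / p$kd1 - p$k2
  if (abs(p$d - dcr) <= tol * max(1, dcr)) {
    states <- data.frame(c_tdc = 0, stability = "stable",
                         stringsAsFactors = FALSE)
    regime <- "critical"
    semi <- TRUE
  } else if (p$d > dcr) {
    states <- data.frame(c_tdc = c(0, pos),
                         stability = c("unstable", "stable"),
                         stringsAsFactors = FALSE)
    regime <- "above_critical"
    semi <- FALSE
  } else {
    states <- data.frame(c_tdc = 0, stability = "stable",
                         stringsAsFactors = FALSE)
    regime <- "below_critical"
    semi <- FALSE
  }
  structure(list(states = states, d_cr = dcr, regime = regime,
                 semistable_at_zero = semi, params = p),
            class = "tdc_steady_states")
}

#' @export
print.tdc_steady_states <- function(x, ...) {
  cat(sprintf("TDC steady states (d = %g, d_cr = %g, regime: %s)\n",
              x$params$d, x$d_cr, x$regime))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Stable TDC density as a function of Delta expression
#'
#' The steady-state response curve: zero up to the critical Delta d_cr, then
#' linear with slope k1/kd1. This is the piecewise-linear relationship between
#' TDC number density and DLL expression by the stem cells.
#'
#' @param d_values Numeric vector of Delta levels (>= 0).
#' @param p A [tdc_params()] object (its own `d` is ignored).
#' @return A data.frame with columns `d`, `c_tdc_stable`, `regime`.
#' @export
tdc_linear_response <- function(d_values, p) {
  if (any(d_values < 0)) stop("Delta levels must be >= 0")
  dcr <- critical_delta(p)
  c_tdc <- pmax(0, p$k1 * d_values / p$kd1 - p$k2)
  regime <- ifelse(d_values > dcr, "above_critical",
                   ifelse(d_values < dcr, "below_critical", "critical"))
  data.frame(d = d_values, c_tdc_stable = c_tdc, regime = regime,
             stringsAsFactors = FALSE)
}

#' Write the (d, C_TDC) response curve to CSV
#'
#' @param curve Data frame from [tdc_linear_response()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tdc_curve <- function(curve, path) {
  write_tidy_csv(curve, path)
}
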