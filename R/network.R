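#' Hill regulatory response
#'
#' General saturating response used for every regulation term of the network.
#' With an activator x and inhibitors y_i it returns
#' x^n / (1 + x^n + sum(y_i^n)); in the pure-repression form (no activator,
#' `activator = NULL`) the numerator is 1, giving 1 / (1 + sum(y_i^n)).
#' Activities are normalized by the half-saturation constant, hence the 1 in
#' the denominator.
#'
#' @param activator Non-negative scalar activator activity, or `NULL` for the
#'   pure-repression form.
#' @param inhibitors Numeric vector (possibly empty) of non-negative inhibitor
#'   activities.
#' @param n Hill coefficient, >= 1.
#' @return A fraction in \[0, 1\].
#' @examples
#' hill_response(1, n = 2)                 # 0.5
#' hill_response(1, c(1, 1), n = 2)        # 0.25
#' hill_response(NULL, 0, n = 2)           # 1, unrepressed repression form
#' @export
hill_response <- function(activator = NULL, inhibitors = numeric(), n = 2) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("Hill coefficient 'n' must be a scalar >= 1")
  if (length(inhibitors) && (!is.numeric(inhibitors) || any(inhibitors < 0)))
    stop("inhibitor activities must be non-negative")
  denom <- 1 + sum(inhibitors^n)
  if (is.null(activator) ||
      (is.character(activator) && identical(activator, "none"))) {
    return(1 / denom)
  }
  if (!is.numeric(activator) || length(activator) != 1L || activator < 0)
    stop("activator activity must be a non-negative scalar")
  activator^n / (denom + activator^n)
}

#' Right-hand side of the four-variable Notch-Wnt-YAP network
#'
#' Time derivatives of the normalized activities. Notch in the TAC is
#' activated by Wnt in the SC and repressed by nuclear YAP and Wnt in the TAC
#' (in-cis Delta expression); Wnt in the SC and nuclear YAP in the TAC are
#' activated by Notch in the TAC; Wnt in the TAC is repressed by Notch in the
#' same cell. Each equation carries a first-order degradation term and a
#' constant generation term.
#'
#' @param state Numeric state vector `(A_Notch, A_WntSC, A_WntTA, A_YAP)`.
#' @param params A [network_params()] object (or plain named list with the
#'   same fields).
#' @return Named numeric vector of the four time derivatives (a.u./time).
#' @export
network_rhs <- function(state, params) {
  if (any(!is.finite(state))) stop("non-finite state passed to network_rhs")
  n <- params$n
  AN <- state[[1L]]; WS <- state[[2L]]; WT <- state[[3L]]; AY <- state[[4L]]
  hN <- AN^n
  c(A_Notch = params$kNotch * WS^n / (1 + WS^n + AY^n + WT^n) -
      params$kdNotch * AN + params$kPNotch,
    A_WntSC = params$kWntSC * hN / (1 + hN) -
      params$kdWntSC * WS + params$kPWntSC,
    A_WntTA = params$kWntTA / (1 + hN) -
      params$kdWntTA * WT + params$kPWntTA,
    A_YAP = params$kYAP * hN / (1 + hN) -
      params$kdYAP * AY + params$kPYAP)
}

#' Analytic Jacobian of the network right-hand side
#'
#' Closed-form 4x4 matrix of partial derivatives of [network_rhs()], used by
#' the Newton correctors and the eigenvalue-based Hopf/fold detection.
#'
#' @inheritParams network_rhs
#' @return A 4x4 numeric matrix with rows/columns in state order.
#' @export
network_jacobian <- function(state, params) {
  if (any(!is.finite(state))) stop("non-finite state passed to network_jacobian")
  n <- params$n
  AN <- state[[1L]]; WS <- state[[2L]]; WT <- state[[3L]]; AY <- state[[4L]]
  # d/dx [x^n] at x = 0 with n > 1 is 0; guard 0^(n-1) for n = 1 exactness
  dpow <- function(x) if (x == 0 && n == 1) 1 else n * x^(n - 1)
  D <- 1 + WS^n + AY^n + WT^n
  J <- matrix(0, 4L, 4L, dimnames = list(state_names(), state_names()))
  # row 1: Notch equation
  J[1L, 1L] <- -params$kdNotch
  J[1L, 2L] <- params$kNotch * dpow(WS) * (D - WS^n) / D^2
  J[1L, 3L] <- -params$kNotch * WS^n * dpow(WT) / D^2
  J[1L, 4L] <- -params$kNotch * WS^n * dpow(AY) / D^2
  # shared derivative of AN^n/(1+AN^n) and of 1/(1+AN^n)
  g <- dpow(AN) / (1 + AN^n)^2
  J[2L, 1L] <- params$kWntSC * g
  J[2L, 2L] <- -params$kdWntSC
  J[3L, 1L] <- -params$kWntTA * g
  J[3L, 3L] <- -params$kdWntTA
  J[4L, 1L] <- params$kYAP * g
  J[4L, 4L] <- -params$kdYAP
  J
}

# analytic derivative of the RHS with respect to one rate constant; every
# rate enters exactly one equation linearly, which keeps continuation exact
param_gradient <- function(state, params, vary) {
  n <- params$n
  AN <- state[[1L]]; WS <- state[[2L]]; WT <- state[[3L]]; AY <- state[[4L]]
  hN <- AN^n
  g <- numeric(4L)
  switch(vary,
    kNotch  = g[1L] <- WS^n / (1 + WS^n + AY^n + WT^n),
    kWntSC  = g[2L] <- hN / (1 + hN),
    kWntTA  = g[3L] <- 1 / (1 + hN),
    kYAP    = g[4L] <- hN / (1 + hN),
    kdNotch = g[1L] <- -AN,
    kdWntSC = g[2L] <- -WS,
    kdWntTA = g[3L] <- -WT,
    kdYAP   = g[4L] <- -AY,
    kPNotch = g[1L] <- 1,
    kPWntSC = g[2L] <- 1,
    kPWntTA = g[3L] <- 1,
    kPYAP   = g[4L] <- 1,
    stop("cannot continue in parameter '", vary, "'")
  )
  g
}

# upper corners of the forward-invariant trapping box kP/kd .. (k + kP)/kd
bounding_box <- function(params) {
  up <- c((params$kNotch + params$kPNotch) / params$kdNotch,
          (params$kWntSC + params$kPWntSC) / params$kdWntSC,
          (params$kWntTA + params$kPWntTA) / params$kdWntTA,
          (params$kYAP + params$kPYAP) / params$kdYAP)
  lo <- c(params$kPNotch / params$kdNotch,
          params$kPWntSC / params$kdWntSC,
          params$kPWntTA / params$kdWntTA,
          params$kPYAP / params$kdYAP)
  list(lower = lo, upper = up)
}
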