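# Shared helpers: independent oracles kept deliberately separate from the
# package's own code paths.

baseline_params <- function(...) network_params(...)

# Independent 1-D reduction oracle for equilibrium counting: at any
# equilibrium the three downstream activities are explicit functions of
# A_Notch, so equilibria are sign changes of a scalar residual on a grid.
equilibrium_count_1d <- function(params, an_max = NULL, n_grid = 20000L) {
  n <- params$n
  if (is.null(an_max))
    an_max <- (params$kNotch + params$kPNotch) / params$kdNotch * 1.2
  an <- seq(1e-9, an_max, length.out = n_grid)
  h <- an^n / (1 + an^n)
  ws <- (params$kWntSC * h + params$kPWntSC) / params$kdWntSC
  wt <- (params$kWntTA * (1 - h) + params$kPWntTA) / params$kdWntTA
  ay <- (params$kYAP * h + params$kPYAP) / params$kdYAP
  g <- params$kNotch * ws^n / (1 + ws^n + ay^n + wt^n) -
    params$kdNotch * an + params$kPNotch
  sum(g[-1] * g[-length(g)] < 0) + sum(g == 0)
}

# finite-difference Jacobian of the network RHS (central, step 1e-6)
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (network_rhs(up, params) - network_rhs(dn, params)) / (2 * h)
  }
  J
}

# Table of published oscillatory ranges used by the acceptance checks
published_ranges <- function() {
  data.frame(
    parameter = c("kNotch", "kWntSC", "kWntTA", "kYAP",
                  "kdNotch", "kdWntSC", "kdWntTA", "kdYAP",
                  "kPNotch", "kPWntSC", "kPWntTA", "kPYAP"),
    low  = c(0.997, 1.397, 0.502, 0.160, 0.187, 0.189, 0.199, 0.020,
             0.050, 0.100, 0.000, 0.087),
    high = c(1.121, 1.506, 1.008, 0.189, 0.200, 0.200, 0.361, 0.021,
             0.058, 0.134, 0.106, 0.100))
}
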