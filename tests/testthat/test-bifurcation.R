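fig5_params <- function() update_params(network_params(),
                                        kWntSC = 0.85, kYAP = 0.02)

test_that("decoupled decay has the unique closed-form equilibrium", {
  p <- network_params(kNotch = 0, kWntSC = 0, kWntTA = 0, kYAP = 0)
  eqs <- find_equilibria(p, n_starts = 16L)
  expect_length(eqs, 1L)
  expect_equal(unname(unclass(eqs[[1]]$state)),
               c(0.05 / 0.2, 0.1 / 0.2, 0.1 / 0.2, 0.1 / 0.02),
               tolerance = 1e-8)
  expect_true(eqs[[1]]$stable)
})

test_that("equilibrium counts match the 1-D reduction oracle", {
  # monostable: baseline pushed out of the oscillatory window
  mono <- update_params(network_params(), kPNotch = 0.20)
  expect_equal(equilibrium_count_1d(mono), 1L)
  expect_length(find_equilibria(mono), 1L)
  # bistable window of the fold parameter set
  bist <- update_params(fig5_params(), kPNotch = 0.058)
  expect_equal(equilibrium_count_1d(bist), 3L)
  eqs <- find_equilibria(bist)
  expect_length(eqs, 3L)
  expect_equal(sum(vapply(eqs, `[[`, logical(1), "stable")), 2L)
  # every root satisfies the residual contract
  for (e in eqs)
    expect_lt(max(abs(network_rhs(e$state, bist))), 1e-10)
})

test_that("continuation finds exactly two Hopf points at the baseline", {
  br <- continue_equilibria(network_params(), "kPNotch", c(0.03, 0.08))
  hp <- hopf_points(br)
  expect_equal(nrow(hp), 2L)
  expect_equal(nrow(fold_points(br)), 0L)
  # at each Hopf the leading complex pair is on the imaginary axis
  p <- network_params()
  for (i in 1:2) {
    p$kPNotch <- hp$param[i]
    x <- as.numeric(hp[i, c("A_Notch", "A_WntSC", "A_WntTA", "A_YAP")])
    ev <- eigen(network_jacobian(x, p), only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    expect_lt(abs(Re(lead)), 1e-6)
    expect_gt(abs(Im(lead)), 1e-6)
  }
})

test_that("stability flags flip exactly at the Hopf points", {
  br <- continue_equilibria(network_params(), "kPNotch", c(0.03, 0.08))
  hp <- sort(hopf_points(br)$param)
  flips <- which(diff(br$stable) != 0)
  expect_length(flips, 2L)
  for (i in 1:2) {
    lo <- min(br$param[flips[i]], br$param[flips[i] + 1L])
    hi <- max(br$param[flips[i]], br$param[flips[i] + 1L])
    expect_true(hp[i] >= lo - 1e-6 && hp[i] <= hi + 1e-6)
  }
})

test_that("a branch without eigenvalue crossings has no special points", {
  br <- continue_equilibria(network_params(), "kPNotch", c(0.09, 0.15))
  expect_equal(nrow(hopf_points(br)), 0L)
  expect_equal(nrow(fold_points(br)), 0L)
  expect_true(all(br$stable))
})

test_that("the bistable parameter set yields two folds with zero eigenvalue", {
  br <- continue_equilibria(fig5_params(), "kPNotch", c(0.01, 0.15))
  fp <- fold_points(br)
  expect_equal(nrow(fp), 2L)
  p <- fig5_params()
  for (i in 1:2) {
    p$kPNotch <- fp$param[i]
    x <- as.numeric(fp[i, c("A_Notch", "A_WntSC", "A_WntTA", "A_YAP")])
    ev <- eigen(network_jacobian(x, p), only.values = TRUE)$values
    crit <- ev[abs(Im(ev)) < 1e-8]
    expect_lt(min(abs(Re(crit))), 1e-6)
  }
  # the middle branch between the folds is unstable
  mid <- br[br$param > min(fp$param) & br$param < max(fp$param), ]
  expect_true(any(!mid$stable))
})

test_that("hysteresis jumps bracket the fold points within one step", {
  p5 <- fig5_params()
  br <- continue_equilibria(p5, "kPNotch", c(0.01, 0.15))
  fp <- sort(fold_points(br)$param)       # LP2 < LP1
  up <- hysteresis_sweep(p5, "kPNotch", c(0.03, 0.09), "up", n_steps = 25L)
  dn <- hysteresis_sweep(p5, "kPNotch", c(0.03, 0.09), "down", n_steps = 25L)
  ju <- sweep_jumps(up); jd <- sweep_jumps(dn)
  expect_equal(nrow(ju), 1L)
  expect_equal(nrow(jd), 1L)
  expect_gt(ju$delta, 0)                  # up-sweep jumps to the high branch
  expect_lt(jd$delta, 0)
  expect_true(ju$from <= fp[2] && fp[2] <= ju$to)
  expect_true(jd$to <= fp[1] && fp[1] <= jd$from)
  # settled states differ on the bistable window, agree outside it
  inside <- up$param > fp[1] + 0.003 & up$param < fp[2] - 0.003
  outside <- up$param < fp[1] - 0.003 | up$param > fp[2] + 0.003
  dn_m <- dn[order(dn$param), ]; up_m <- up[order(up$param), ]
  expect_gt(max(abs(up_m$A_Notch[inside] - dn_m$A_Notch[inside])), 0.5)
  expect_lt(max(abs(up_m$A_Notch[outside] - dn_m$A_Notch[outside])), 1e-5)
})

test_that("sweeps restricted to one side of the folds show no jumps", {
  p5 <- fig5_params()
  up <- hysteresis_sweep(p5, "kPNotch", c(0.08, 0.12), "up", n_steps = 9L)
  dn <- hysteresis_sweep(p5, "kPNotch", c(0.08, 0.12), "down", n_steps = 9L)
  expect_equal(nrow(sweep_jumps(up)), 0L)
  expect_equal(nrow(sweep_jumps(dn)), 0L)
  up_m <- up[order(up$param), ]; dn_m <- dn[order(dn$param), ]
  expect_lt(max(abs(up_m$A_Notch - dn_m$A_Notch)), 1e-6)
})

test_that("Hopf interval agrees with the simulated oscillation boundary", {
  r <- oscillatory_range(network_params(), "kPNotch", c(0.03, 0.08))
  mid <- (r$low + r$high) / 2
  a_mid <- epiosc:::notch_amplitude_at(network_params(), "kPNotch", mid)
  expect_gt(a_mid, 0.1)
  # 2 percent of the parameter value on either side of each Hopf point
  for (edge in c(r$low, r$high)) {
    inside <- edge + 0.02 * edge * (if (edge == r$low) 1 else -1)
    outside <- edge - 0.02 * edge * (if (edge == r$low) 1 else -1)
    expect_gt(epiosc:::notch_amplitude_at(network_params(), "kPNotch",
                                          inside), 0.1 * a_mid)
    expect_lt(epiosc:::notch_amplitude_at(network_params(), "kPNotch",
                                          outside), 0.1 * a_mid)
  }
})

test_that("oscillatory_range reports a structured error off the window", {
  expect_error(
    oscillatory_range(network_params(), "kPNotch", c(0.09, 0.15)),
    "found 0")
  tab <- scan_table(symbols = character())
  expect_equal(nrow(tab), 0L)
})
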