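test_that("hill_response evaluates activating and repressing forms", {
  expect_equal(hill_response(0, n = 2), 0)
  expect_equal(hill_response(1, n = 2), 0.5)
  expect_equal(hill_response(NULL, 0, n = 2), 1)
  expect_equal(hill_response("none", 0, n = 2), 1)
  expect_equal(hill_response(1, c(1, 1), n = 2), 0.25)
  # always a proper fraction
  for (i in 1:20) {
    x <- runif(1, 0, 10); y <- runif(3, 0, 10)
    v <- hill_response(x, y, n = 2)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(hill_response(-1, n = 2), "non-negative")
  expect_error(hill_response(1, n = 0.5), ">= 1")
  expect_error(hill_response(1, c(-1), n = 2), "non-negative")
})

test_that("network_rhs matches hand evaluation at the origin", {
  p <- baseline_params()
  expect_equal(unname(network_rhs(c(0, 0, 0, 0), p)),
               c(0.05, 0.1, 1.1, 0.1))
})

test_that("network_rhs null system and pure decay behave as expected", {
  null_p <- network_params(kNotch = 0, kWntSC = 0, kWntTA = 0, kYAP = 0,
                           kPNotch = 0, kPWntSC = 0, kPWntTA = 0, kPYAP = 0)
  expect_equal(unname(network_rhs(c(0, 0, 0, 0), null_p)), rep(0, 4))
  s <- c(1, 2, 3, 4)
  expect_true(all(network_rhs(s, null_p) < 0))
  expect_equal(unname(network_rhs(s, null_p)),
               -c(0.2, 0.2, 0.2, 0.02) * s)
  expect_error(network_rhs(c(NA, 0, 0, 0), baseline_params()), "non-finite")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(network_params(kdNotch = -1), "> 0")
  expect_error(network_params(kdYAP = 0), "> 0")
  expect_error(network_params(kNotch = -0.1), ">= 0")
  expect_error(network_params(n = 0), ">= 1")
  expect_error(update_params(baseline_params(), bogus = 1), "unknown")
  expect_message(network_params(n = 2.5), "non-integer")
})

test_that("analytic Jacobian agrees with finite differences", {
  set.seed(42)
  p <- baseline_params()
  for (i in 1:100) {
    s <- runif(4, 0, 10)
    J <- network_jacobian(s, p)
    Jfd <- fd_jacobian(s, p)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  }
  # also away from the default Hill coefficient
  p3 <- network_params(n = 3)
  s <- c(0.7, 1.3, 2.1, 4.2)
  expect_lt(max(abs(network_jacobian(s, p3) - fd_jacobian(s, p3))), 1e-4)
})

test_that("Jacobian structural zeros at A_Notch = 0 and decoupled decay", {
  p <- baseline_params()
  J <- network_jacobian(c(0, 1, 1, 1), p)
  # derivative of x^2/(1+x^2) and 1/(1+x^2) vanish at x = 0
  expect_equal(unname(J[2:4, 1]), rep(0, 3))
  p0 <- network_params(kNotch = 0, kWntSC = 0, kWntTA = 0, kYAP = 0)
  J0 <- network_jacobian(c(1, 1, 1, 1), p0)
  expect_equal(unname(J0), diag(c(-0.2, -0.2, -0.2, -0.02)))
})

test_that("non-negativity is forward-invariant on the boundary", {
  set.seed(7)
  for (i in 1:50) {
    p <- network_params(kNotch = runif(1, 0, 2), kWntSC = runif(1, 0, 2),
                        kWntTA = runif(1, 0, 2), kYAP = runif(1, 0, 2),
                        kdNotch = runif(1, 0.1, 1), kdWntSC = runif(1, 0.1, 1),
                        kdWntTA = runif(1, 0.1, 1), kdYAP = runif(1, 0.1, 1),
                        kPNotch = runif(1, 0, 0.5), kPWntSC = runif(1, 0, 0.5),
                        kPWntTA = runif(1, 0, 0.5), kPYAP = runif(1, 0, 0.5))
    s <- runif(4, 0, 5)
    zero <- sample(1:4, sample(1:4, 1))
    s[zero] <- 0
    f <- network_rhs(s, p)
    expect_true(all(f[zero] >= 0))
  }
})

test_that("trajectories enter the degradation-bounded box", {
  set.seed(11)
  for (i in 1:5) {
    p <- network_params(kNotch = runif(1, 0.2, 2), kWntSC = runif(1, 0.2, 2),
                        kWntTA = runif(1, 0.2, 2), kYAP = runif(1, 0.2, 2),
                        kdNotch = runif(1, 0.2, 1), kdWntSC = runif(1, 0.2, 1),
                        kdWntTA = runif(1, 0.2, 1), kdYAP = runif(1, 0.2, 1),
                        kPNotch = runif(1, 0, 0.3), kPWntSC = runif(1, 0, 0.3),
                        kPWntTA = runif(1, 0, 0.3), kPYAP = runif(1, 0, 0.3))
    start <- activity_state(runif(1, 0, 8), runif(1, 0, 8),
                            runif(1, 0, 8), runif(1, 0, 8))
    traj <- integrate_network(p, start, t_end = 150, dt = 1,
                              method = "lsoda")
    final <- as.numeric(traj[nrow(traj), c("A_Notch", "A_WntSC",
                                           "A_WntTA", "A_YAP")])
    lo <- c(p$kPNotch / p$kdNotch, p$kPWntSC / p$kdWntSC,
            p$kPWntTA / p$kdWntTA, p$kPYAP / p$kdYAP)
    hi <- c((p$kNotch + p$kPNotch) / p$kdNotch,
            (p$kWntSC + p$kPWntSC) / p$kdWntSC,
            (p$kWntTA + p$kPWntTA) / p$kdWntTA,
            (p$kYAP + p$kPYAP) / p$kdYAP)
    expect_true(all(final >= lo - 1e-6 & final <= hi + 1e-6))
  }
})

test_that("parameter configs round-trip through YAML and JSON", {
  p <- network_params(kPNotch = 0.061, n = 2)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(as.list(q), as.list(p))
    unlink(f)
  }
  expect_error(as_network_params(list(kFoo = 1)), "kFoo")
})
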