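test_that("integration reproduces closed-form exponential decay", {
  p <- network_params(kNotch = 0, kWntSC = 0, kWntTA = 0, kYAP = 0,
                      kPNotch = 0, kPWntSC = 0, kPWntTA = 0, kPYAP = 0,
                      kdNotch = 0.2, kdWntSC = 0.3, kdWntTA = 0.4,
                      kdYAP = 0.05)
  traj <- integrate_network(p, activity_state(1, 1, 1, 1), t_end = 40,
                            dt = 0.25)
  kd <- c(0.2, 0.3, 0.4, 0.05)
  for (j in 1:4) {
    expected <- exp(-kd[j] * traj$time)
    expect_lt(max(abs(traj[[j + 1L]] - expected)), 1e-6)
  }
})

test_that("halving solver tolerances barely moves the final state", {
  p <- network_params()
  t1 <- integrate_network(p, t_end = 600, rtol = 1e-8, atol = 1e-10)
  t2 <- integrate_network(p, t_end = 600, rtol = 5e-9, atol = 5e-11)
  f1 <- as.numeric(t1[nrow(t1), -1]); f2 <- as.numeric(t2[nrow(t2), -1])
  expect_lt(max(abs(f1 - f2) / pmax(abs(f2), 1e-8)), 1e-6)
})

test_that("metrics recover the period of a synthetic sinusoid", {
  tt <- seq(0, 200, by = 0.1)
  per <- 17.3
  df <- data.frame(time = tt,
                   A_Notch = 1 + 0.5 * sin(2 * pi * tt / per),
                   A_WntSC = 2 + 0.3 * sin(2 * pi * tt / per + 1),
                   A_WntTA = 1 + 0.4 * cos(2 * pi * tt / per),
                   A_YAP = 3 + 0.2 * sin(2 * pi * tt / per))
  m <- oscillation_metrics(df)
  expect_lt(abs(m$variables$A_Notch$period - per) / per, 0.01)
  expect_true(m$sustained)
  expect_equal(m$variables$A_Notch$amplitude, 1.0, tolerance = 1e-3)
})

test_that("constant trajectories are not flagged as sustained", {
  df <- data.frame(time = 0:100, A_Notch = 1, A_WntSC = 1, A_WntTA = 1,
                   A_YAP = 1)
  m <- oscillation_metrics(df)
  expect_false(m$sustained)
  expect_equal(m$variables$A_Notch$amplitude, 0)
  expect_true(is.na(m$variables$A_Notch$period))
  expect_error(phase_relations(m), "sustained")
})

test_that("the oscillatory baseline sustains a common-period limit cycle", {
  traj <- integrate_network(network_params(), t_end = 3000)
  m <- oscillation_metrics(traj)
  expect_true(m$sustained)
  periods <- vapply(m$variables, function(v) v$period, numeric(1))
  expect_lt(diff(range(periods)) / mean(periods), 0.02)
  # peaks and troughs alternate: one trough between consecutive Notch peaks
  pk <- m$variables$A_Notch$peak_times
  tr <- m$variables$A_Notch$trough_times
  expect_gte(length(pk), 2L)
  for (i in seq_len(length(pk) - 1L))
    expect_equal(sum(tr > pk[i] & tr < pk[i + 1L]), 1L)
})

test_that("a generation rate outside the oscillatory range kills the cycle", {
  p <- network_params(kPNotch = 0.10)
  traj <- integrate_network(p, t_end = 3000)
  m <- oscillation_metrics(traj)
  expect_false(m$variables$A_Notch$sustained)
  expect_lt(m$variables$A_Notch$amplitude, 1e-3)
})

test_that("phase relations match the limit-cycle geometry", {
  traj <- integrate_network(network_params(), t_end = 3000)
  m <- oscillation_metrics(traj)
  pr <- phase_relations(m)
  rel <- function(a, b) pr$relation[pr$var_a == a & pr$var_b == b]
  # a variable against itself is aligned at zero offset
  expect_equal(rel("A_Notch", "A_Notch"), "aligned")
  expect_equal(pr$peak_offset[pr$var_a == "A_Notch" &
                                pr$var_b == "A_Notch"], 0)
  # TAC Notch peaks sit on TAC Wnt troughs
  expect_equal(rel("A_Notch", "A_WntTA"), "anti_phase")
  # Notch peaks co-occur with high nuclear YAP
  expect_equal(rel("A_Notch", "A_YAP"), "aligned")
  w <- as.data.frame(traj)
  w <- w[w$time >= 1500, ]
  yap_at_notch_peaks <- vapply(m$variables$A_Notch$peak_times, function(t)
    w$A_YAP[which.min(abs(w$time - t))], numeric(1))
  expect_true(all(yap_at_notch_peaks > mean(range(w$A_YAP))))
})

test_that("total activity decays when generation and regulation are off", {
  p <- network_params(kNotch = 0, kWntSC = 0, kWntTA = 0, kYAP = 0,
                      kPNotch = 0, kPWntSC = 0, kPWntTA = 0, kPYAP = 0)
  traj <- integrate_network(p, activity_state(2, 1, 3, 4), t_end = 50,
                            dt = 0.5)
  total <- rowSums(traj[, -1])
  expect_true(all(diff(total) <= 1e-12))
})

test_that("ablating YAP production stops the cycle in the printed pattern", {
  ab <- ablation_experiment(network_params(),
                            protocol = ablation_protocol(t_switch = 2100),
                            t_end = 4200)
  expect_lt(ab$equilibrium_residual, 1e-9)
  # post-ablation oscillation dies out
  m_post <- oscillation_metrics(ab$post, burn_in_fraction = 0.5)
  expect_false(m_post$variables$A_Notch$sustained)
  expect_lt(m_post$variables$A_Notch$amplitude, 1e-3)
  # printed qualitative ordering relative to pre-switch time averages
  expect_gt(ab$equilibrium[["A_Notch"]], ab$pre_means[["A_Notch"]])
  expect_gt(ab$equilibrium[["A_WntSC"]], ab$pre_means[["A_WntSC"]])
  expect_lt(ab$equilibrium[["A_WntTA"]], ab$pre_means[["A_WntTA"]])
  expect_lt(ab$equilibrium[["A_YAP"]], 1e-6)
})

test_that("an empty ablation protocol leaves one continuous limit cycle", {
  ab <- ablation_experiment(network_params(),
                            protocol = ablation_protocol(
                              t_switch = 1500, ablated_terms = character()),
                            t_end = 3000)
  # state is continuous and the cycle persists after the no-op switch
  joint <- rbind(as.data.frame(ab$pre), as.data.frame(ab$post)[-1L, ])
  m <- oscillation_metrics(joint)
  expect_true(m$variables$A_Notch$sustained)
  expect_error(ablation_protocol(ablated_terms = "kNotch"), "restricted")
})
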