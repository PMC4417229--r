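test_that("the somatic pump follows its printed voltage and Na+ dependence", {
  # numerator zero at V = -75
  expect_equal(soma_pump(-75, 50, 1, 40)$i_pump, 0)
  # at Na_i = K_Na the exponential factor is (1 + e^0) = 2
  v <- -60
  expect_equal(soma_pump(v, 40, 1, 40)$i_pump,
               1000 * (v + 75) / (2 * (v + 80)), tolerance = 1e-12)
  # 3:-2 stoichiometry whenever the pump current is nonzero
  p <- soma_pump(-60, 45, 1, 40)
  expect_equal(p$i_pump_na / p$i_pump_k, -3 / 2)
  expect_equal(p$i_pump_na, 3 * p$i_pump)
  # the singularity at V = -80 is guarded, not infinite
  expect_true(is.finite(soma_pump(-80, 45, 1, 40)$i_pump))
  # far below the affinity constant the pump is off
  expect_equal(soma_pump(-60, 10, 1, 40)$i_pump, 0, tolerance = 1e-6)
})

test_that("the dendritic pump saturates hyperbolically on extracellular K+", {
  # half-activation at K_o = 2.245 mM
  expect_equal(dendrite_pump(2.245, 0.001)$i_pump, 1000 * 0.001 / 2)
  # saturation at high K_o
  expect_equal(dendrite_pump(1e9, 0.001)$i_pump, 1, tolerance = 1e-6)
  expect_equal(dendrite_pump(2.245, 0)$i_pump, 0)
  p <- dendrite_pump(2.5, 0.001)
  expect_equal(p$i_pump_na / p$i_pump_k, -3 / 2)
})

test_that("counterbalance pair: slight somatic mismatch, exact dendritic cancellation", {
  s <- counterbalance_currents(compartment = "soma")
  # net mismatch -0.011 mA/cm2 = -11 uA/cm2, a small depolarizing surplus
  expect_equal(s$i_pump_net + s$i_ex_net, -11, tolerance = 1e-9)
  expect_equal(s$i_ex_net, -511)
  expect_equal(s$i_pump_net, 500)
  expect_equal(s$i_ex_na, -3 * 511)
  d <- counterbalance_currents(compartment = "dendrite")
  expect_equal(d$i_pump_net + d$i_ex_net, 0, tolerance = 1e-12)
  z <- counterbalance_currents(pump_exchanger_set(
    d_pump_s = 0, d_pump_d = 0, g_ex_s = 0, g_pump_s = 0,
    g_ex_d = 0, g_pump_d = 0), "soma")
  expect_true(all(unlist(z) == 0))
})

test_that("somatic shell Ca2+ obeys its update law and 100 nM floor", {
  # at the floor with no current, the clamp holds
  expect_equal(step_soma_ca(1e-4, 0, 0.025), 1e-4)
  # single step against a hand evaluation of the update law
  faraday <- 96485.33212
  ca <- 2e-3; i <- -1; dt <- 0.025
  expected <- ca + dt * (-10 * i / (2 * faraday * 0.1) - 1 * ca)
  expect_equal(step_soma_ca(ca, i, dt), expected, tolerance = 1e-12)
  # with no current, Ca decays monotonically toward the floor
  ca <- 5e-3; path <- numeric(200)
  for (k in 1:200) path[k] <- ca <- step_soma_ca(ca, 0, 0.025)
  expect_true(all(diff(path) <= 0))
  expect_gte(min(path), 1e-4)
})

test_that("dendritic shell Ca2+ rectifies outward current and finds its resting point", {
  # outward (positive) Ca2+ current contributes nothing (chan clamped at 0)
  ca <- 2e-3; dt <- 0.025
  expect_equal(step_dend_ca(ca, +50, dt), step_dend_ca(ca, 0, dt))
  # single step against a hand evaluation
  faraday <- 96485.33212
  i <- -2; depth <- 0.616
  chan <- -10 * i / (2 * faraday * depth)
  expected <- ca + dt * (chan - 4e-5 * ca / (ca + 4e-5) + (4e-5 - ca) / 2)
  expect_equal(step_dend_ca(ca, i, dt), expected, tolerance = 1e-12)
  # zero-current equilibrium matches an independent root-finding oracle
  root <- uniroot(function(c) -4e-5 * c / (c + 4e-5) + (4e-5 - c) / 2,
                  c(1e-8, 4e-5), tol = 1e-14)$root
  ca <- 1e-3
  for (k in 1:5000) ca <- step_dend_ca(ca, 0, 0.1)
  expect_equal(ca, root, tolerance = 1e-9)
})

test_that("intracellular Na+ integrates the delayed net current with its floors", {
  # zero net current pins Na_i at the 10 mM floor
  expect_equal(step_na_i(10, 0, 0.025)$na_i, 10)
  expect_equal(step_na_i(10, -100, 0.025)$na_i, 10)
  # constant influx: growth rate matches the closed linear form
  faraday <- 96485.33212
  k <- 40 / (faraday * 22)
  out <- step_na_i(20, 50, 0.025)
  expect_equal(out$na_i, 20 + 0.025 * k * 50, tolerance = 1e-12)
  # E_Na floors at +70 mV once Na_i rises
  expect_equal(step_na_i(40, 0, 0.025)$e_na, 70)
  # just above the floor, E_Na follows the Nernst relation
  expect_equal(step_na_i(10, 0, 0.025)$e_na, nernst_potential(140, 10))
})

test_that("extracellular K+ integrates the efflux/uptake balance inside its band", {
  # zero net current leaves K_o unchanged
  expect_equal(step_k_o(2.5, 5, 5, 0.025), 2.5)
  # single-step hand evaluation
  faraday <- 96485.33212
  expected <- 2.5 + 0.025 * 0.0119 * (30 - 5) / (faraday * 0.07)
  expect_equal(step_k_o(2.5, 30, 5, 0.025), expected, tolerance = 1e-12)
  # sustained outward K+ saturates at the 3.03 mM ceiling
  ko <- 2.5
  for (i in 1:3000) ko <- step_k_o(ko, 300, 0, 1)
  expect_equal(ko, 3.03)
  # sustained uptake floors at 2 mM
  ko <- 2.5
  for (i in 1:3000) ko <- step_k_o(ko, 0, 300, 1)
  expect_equal(ko, 2)
})

test_that("the delay line is an exact tau-lag FIFO pre-filled with zeros", {
  dt <- 0.5; tau <- 100
  x <- c(rep(0, 10), 1, rep(0, 500))   # impulse
  y <- na_delay_line(x, tau, dt)
  lag <- round(tau / dt)
  expect_equal(which(y == 1), which(x == 1) + lag)
  expect_true(all(y[seq_len(lag)] == 0))
  # arbitrary signal: output is the input shifted by exactly tau
  set.seed(8)
  x <- rnorm(4000)
  y <- na_delay_line(x, tau, dt)
  expect_identical(y[(lag + 1):4000], x[1:(4000 - lag)])
  # cross-correlation peaks at the programmed lag
  cc <- ccf(y, x, lag.max = 400, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], lag)
})
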