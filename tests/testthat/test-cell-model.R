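test_that("axial currents are antisymmetric and match the series-resistance formula", {
  cell <- purkinje_cell()
  eq <- axial_currents(-65, -65, cell)
  expect_equal(eq$i_ds_nA, 0)
  expect_equal(eq$i_sd_nA, 0)
  ax <- axial_currents(-65, -45, cell)
  expect_equal(ax$i_ds_nA, -ax$i_sd_nA)  # charge conservation
  expect_gt(ax$i_ds_nA, 0)               # depolarized dendrite feeds the soma
  # published geometry at Ra = 35.4 Ohm cm against a hand evaluation
  ra_um <- 35.4e4
  oracle <- (ra_um * 11 / (pi * 11^2) +
             ra_um * (529.29 / 2) / (pi * 1.61^2)) / 1e6
  expect_equal(ax$r_Mohm, oracle, tolerance = 1e-9)
  expect_equal(ax$i_ds_nA, 20 / oracle, tolerance = 1e-9)
})

test_that("constructor rejects unknown and negative parameters", {
  expect_error(purkinje_cell(no_such_parameter = 1), "unknown parameter")
  expect_error(purkinje_cell(g_bk_s = -1), "negative density")
  # overrides land on the final parameter set
  cell <- purkinje_cell(k_na = 12)
  expect_equal(cell$params$k_na, 12)
})

test_that("dendritic defaults carry the correction factor", {
  cell <- purkinje_cell()
  expect_equal(cell$params$g_ka, 32 * 6.16)
  expect_equal(cell$params$cm_d, 0.8 * 6.16)
  expect_equal(cell$params$depth_d, 0.1 * 6.16)
  expect_equal(cell$params$g_bk_s, 72.86)   # soma untouched by cd
  half <- purkinje_cell(cd = 3.08)
  expect_equal(half$params$g_ka, 32 * 3.08)
})

test_that("a zero-duration simulation returns the initial state only", {
  tr <- simulate_cell(purkinje_cell(), 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$v_soma, -65)
  expect_equal(tr$v_dend, -65)
  expect_equal(tr$na_i, 10)
  expect_equal(tr$k_o, 2)
})

test_that("simulation is deterministic: identical configs give identical traces", {
  a <- simulate_cell(purkinje_cell(), 0.5)
  b <- simulate_cell(purkinje_cell(), 0.5)
  expect_identical(a$v_soma, b$v_soma)
  expect_identical(a$v_dend, b$v_dend)
  expect_identical(attr(a, "final_state"), attr(b, "final_state"))
})

test_that("the state change vanishes as dt -> 0 (first-order consistency)", {
  tr <- simulate_cell(purkinje_cell(), duration_s = 2e-6, dt_ms = 1e-3,
                      stride = 1L)
  expect_lt(max(abs(tr$v_soma - (-65))), 0.05)
  expect_lt(max(abs(tr$v_dend - (-65))), 0.05)
  # halving the window halves the change (no jump at dt -> 0)
  tr2 <- simulate_cell(purkinje_cell(), duration_s = 1e-6, dt_ms = 1e-3,
                       stride = 1L)
  expect_lt(max(abs(tr2$v_dend - (-65))),
            0.6 * max(abs(tr$v_dend - (-65))))
})

test_that("an all-passive configuration matches the closed-form two-compartment RC solution", {
  zero_g <- list(g_nar = 0, g_kfast = 0, g_kmid = 0, g_kslow = 0,
                 g_cap_s = 0, g_ih_s = 0, g_bk_s = 0, g_sk = 0,
                 g_cat = 0, g_cae = 0, g_cap_d = 0, g_ih_d = 0,
                 g_kv12 = 0, g_ka = 0, g_km = 0, g_kd = 0, g_dr = 0,
                 g_bk_d = 0, g_k2 = 0, g_erg = 0,
                 d_pump_s = 0, d_pump_d = 0, g_ex_s = 0, g_pump_s = 0,
                 g_ex_d = 0, g_pump_d = 0,
                 tau_na_s = 1e-4)  # shrink the (inert) Na+ delay buffer
  cell <- do.call(purkinje_cell, zero_g)
  p <- cell$params
  # start away from equilibrium by offsetting the dendrite
  init <- purkinje2c:::.initial_state(cell)
  init$v_dend <- -55
  dt <- 2e-6
  tr <- simulate_cell(cell, duration_s = 5e-3, dt_ms = dt, stride = 250000L,
                      init = init)
  # closed form: dV/dt = A (V - V_inf) with the leak/axial conductance matrix
  cax_s <- 1e-3 / (p$r_coupling_Mohm * p$area_s_cm2)
  cax_d <- 1e-3 / (p$r_coupling_Mohm * p$area_d_cm2)
  A <- rbind(c(-(p$g_leak_s + cax_s), cax_s) / p$cm_s,
             c(cax_d, -(p$g_leak_d + cax_d)) / p$cm_d)
  bvec <- c(p$g_leak_s * p$e_leak_s / p$cm_s,
            p$g_leak_d * p$e_leak_d / p$cm_d)
  veq <- solve(A, -bvec)
  eg <- eigen(A)
  v0 <- c(-65, -55)
  co <- solve(eg$vectors, v0 - veq)
  exact <- function(t_ms)
    veq + as.vector(eg$vectors %*% (co * exp(eg$values * t_ms)))
  amp <- max(abs(v0 - veq))
  for (k in seq_len(nrow(tr))) {
    ex <- exact(tr$t_ms[k])
    expect_lt(abs(tr$v_soma[k] - ex[1]) / amp, 1e-6)
    expect_lt(abs(tr$v_dend[k] - ex[2]) / amp, 1e-6)
  }
})

test_that("ion clamps hold at every recorded sample of a spiking run", {
  tr <- simulate_cell(purkinje_cell(), 3)
  tr <- tr[-1, ]  # the printed initial [Ca] (50 nM) predates the clamp
  expect_gte(min(tr$ca_soma), 1e-4 - 1e-15)
  expect_gte(min(tr$na_i), 10)
  expect_gte(min(tr$e_na), 70)
  expect_true(all(tr$k_o >= 2 & tr$k_o <= 3.03))
  expect_true(all(tr$o_nar >= 0 & tr$o_nar <= 1))
  expect_true(all(is.finite(tr$v_soma) & is.finite(tr$v_dend)))
})

test_that("the default model fires spontaneously at Purkinje-like rates", {
  tr <- simulate_cell(purkinje_cell(), 2)
  sp <- detect_spikes(tr)
  expect_gt(length(sp), 50)          # tens of Hz or more, unprompted
  expect_gt(max(tr$v_soma), 0)       # overshooting action potentials
  expect_lt(min(tr$v_soma), -70)     # afterhyperpolarizations
})

test_that("trace summaries and printing run cleanly", {
  tr <- simulate_cell(purkinje_cell(), 2)
  expect_output(print(tr), "purkinje_trace")
  s <- summary(tr)
  expect_output(print(s), "somatic spikes")
  expect_gt(s$n_spikes_soma, 0)
})
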