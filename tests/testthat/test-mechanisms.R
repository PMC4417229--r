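# gate inventory: current, gate, type (act = activation, inact =
# inactivation), and the Ca2+ argument where required
.gate_table <- data.frame(
  current = c("K_fast", "K_fast", "K_mid", "K_slow", "CaP_s", "Ih_s",
              "BK_s", "BK_s", "CaT", "CaT", "CaE", "CaE", "CaP_d", "Ih_d",
              "Kv12", "KA", "KA", "KM", "KD", "KD", "DR", "BK_d", "K2",
              "ERG", "ERG"),
  gate = c("m", "h", "m", "m", "m", "m", "m", "h", "m", "h", "m", "h",
           "m", "m", "m", "m", "h", "m", "m", "h", "m", "m", "m", "m",
           "h"),
  type = c("act", "inact", "act", "act", "act", "inact", "act", "inact",
           "act", "inact", "act", "inact", "act", "inact", "act", "act",
           "inact", "act", "act", "inact", "act", "act", "act", "act",
           "inact"),
  stringsAsFactors = FALSE)

test_that("steady-state gates are bounded, monotone and have positive time constants", {
  vs <- seq(-120, 60, by = 2.5)
  for (k in seq_len(nrow(.gate_table))) {
    cur <- .gate_table$current[k]; g <- .gate_table$gate[k]
    vals <- t(vapply(vs, function(v) gate_inf_tau(cur, g, v), numeric(2)))
    expect_true(all(vals[, "inf"] >= 0 & vals[, "inf"] <= 1),
                info = paste(cur, g, "inf in [0,1]"))
    expect_true(all(vals[, "tau"] > 0), info = paste(cur, g, "tau > 0"))
    d <- diff(vals[, "inf"])
    if (.gate_table$type[k] == "act")
      expect_true(all(d >= -1e-12), info = paste(cur, g, "increasing"))
    else
      expect_true(all(d <= 1e-12), info = paste(cur, g, "decreasing"))
  }
})

test_that("Boltzmann gates sit at their midpoint value at V_half", {
  # plain sigmoids reach 0.5; gates with a printed floor reach
  # floor + (1 - floor)/2
  expect_equal(gate_inf_tau("K_fast", "m", -24)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("K_mid", "m", -24)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("K_slow", "m", -16.5)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("CaP_s", "m", -19)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("Ih_s", "m", -90.1)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("BK_s", "m", -28.9)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("K_fast", "h", -5.8)[["inf"]], 0.31 + 0.69 / 2)
  expect_equal(gate_inf_tau("BK_s", "h", -32)[["inf"]], 0.085 + 0.915 / 2)
  # ERG activation midpoint is the shifted -5 mV
  expect_equal(gate_inf_tau("ERG", "m", -5)[["inf"]], 0.5)
})

test_that("Ca2+-gated z gates hit half-activation at their printed set points", {
  expect_equal(gate_inf_tau("BK_s", "z", -60, ca_mm = 0.001)[["inf"]], 0.5)
  expect_equal(gate_inf_tau("SK", "z", -60, ca_mm = 0.00019)[["inf"]], 0.5)
  # SK z is a 4th-power Hill function: (0.00019/ca)^4
  ca <- 4e-4
  expect_equal(gate_inf_tau("SK", "z", 0, ca)[["inf"]],
               1 / (1 + (0.00019 / ca)^4))
  expect_error(gate_inf_tau("BK_s", "z", -60), "Ca")
})

test_that("the delayed-rectifier catch branch removes the singularity at -55 mV", {
  # alpha(-55) = 0.1 * 10 * (1 - 0/2) = 1 via the catch branch
  b55 <- 0.125 * exp(-(-55 + 65) / 80)
  expect_equal(gate_inf_tau("DR", "m", -55)[["inf"]], 1 / (1 + b55))
  # continuity across the removable singularity
  near <- vapply(c(-55 - 1e-5, -55, -55 + 1e-5),
                 function(v) gate_inf_tau("DR", "m", v)[["inf"]], numeric(1))
  expect_lt(max(abs(near - near[2])), 1e-6)
})

test_that("unknown gate ids are rejected", {
  expect_error(gate_inf_tau("K_fast", "z", -60), "unknown gate")
  expect_error(gate_inf_tau("NoSuch", "m", -60), "unknown current")
})

test_that("the literal-sigmoid audit mode reproduces the printed 1/exp form", {
  v <- -10; vh <- -24; k <- 15.4
  lit <- gate_inf_tau("K_fast", "m", v, literal_sigmoid = TRUE)[["inf"]]
  expect_equal(lit, exp((v - vh) / k))
  expect_gt(lit, 1)  # the printed form exceeds 1 above V_half
})

test_that("GHK flux vanishes with zero permeability and matches the analytic V=0 limit", {
  expect_identical(ghk_flux(-20, perm_cm_s = 0), 0)
  faraday <- 96485.33212
  limit <- 1e-3 * 5e-5 * 2 * faraday * (1e-4 - 2)
  expect_equal(ghk_flux(0), limit, tolerance = 1e-12)
  # continuity at the removable singularity
  expect_equal(ghk_flux(1e-7), limit, tolerance = 1e-6)
  expect_equal(ghk_flux(-1e-7), limit, tolerance = 1e-6)
  # inward (negative) at physiological potentials since [Ca]o >> [Ca]i
  expect_lt(ghk_flux(-60), 0)
  # independent direct evaluation away from the singularity
  v <- -0.06; u <- 2 * faraday * v / (8.314462618 * 295)
  direct <- 1e-3 * 5e-5 * 4 * faraday^2 * v / (8.314462618 * 295) *
    (1e-4 - 2 * exp(-u)) / (1 - exp(-u))
  expect_equal(ghk_flux(-60), direct, tolerance = 1e-10)
})

test_that("eval_current follows the gate compositions and sign conventions", {
  # zero conductance silences every mechanism
  for (id in c("K_fast", "BK_s", "SK", "CaT", "DR", "ERG", "Leak_s"))
    expect_identical(
      eval_current(id, c(m = 0.5, h = 0.5, z = 0.5), 0, -30, -88), 0)
  # ohmic currents vanish at the reversal potential
  expect_equal(eval_current("KA", c(m = 0.3, h = 0.2), 197.12, -77, -77), 0)
  # soma leak: g = 0.1 mS/cm2, V = -60, E_L = -70 -> +1 uA/cm2 outward
  expect_equal(eval_current("Leak_s", numeric(0), 0.1, -60, -70), 1)
  # resurgent Na+ is gated by the open-state occupancy alone
  expect_equal(eval_current("NaR", c(O = 0.2), 156, -20, 70),
               156 * 0.2 * (-90))
  # composition exponents: BK_s is m^3 z^2 h
  g <- c(m = 0.5, z = 0.5, h = 0.5)
  expect_equal(eval_current("BK_s", g, 72.86, -20, -88),
               72.86 * 0.5^3 * 0.5^2 * 0.5 * 68)
  expect_error(eval_current("K_fast", c(m = 0.5), 41.6, -20, -88),
               "missing gate")
})

test_that("temperature factors match their closed forms", {
  # dendritic rates carry 3^((36-37)/10); verified through a tau ratio
  mt <- 3^(-0.1)
  v <- -40
  am <- 1.4 / (1 + exp(-(v + 27) / 12))
  bm <- 0.49 / (1 + exp((v + 30) / 4))
  expect_equal(gate_inf_tau("KA", "m", v)[["tau"]], 1 / ((am + bm) * mt),
               tolerance = 1e-12)
  # Kv1.2 uses 2^.. base-3 factor referenced to 22 C
  mtk <- 3^((36 - 22) / 10)
  ak <- 0.12899 * exp((v + 45) / 33.90877)
  bk <- 0.12899 * exp(-(v + 45) / 12.42101)
  expect_equal(gate_inf_tau("Kv12", "m", v)[["tau"]],
               1 / ((ak + bk) * mtk), tolerance = 1e-12)
  # the M-current factor 2.3^((T-36)/10) is exactly 1 at 36 C
  expect_equal(gate_inf_tau("KM", "m", -35)[["tau"]],
               1000 / (3.3 * (exp(0) + exp(0))), tolerance = 1e-12)
})

test_that("somatic time constants are returned in ms (seconds-scale tables converted)", {
  # K_fast tau_m at -60 mV: 1000*(0.000103 + 0.0149*exp(0.035*-60))
  expect_equal(gate_inf_tau("K_fast", "m", -60)[["tau"]],
               1000 * (0.000103 + 0.0149 * exp(0.035 * -60)),
               tolerance = 1e-12)
  # branch selection at the printed -35 mV threshold
  expect_equal(gate_inf_tau("K_fast", "m", -30)[["tau"]],
               1000 * (0.000129 + 1 / (exp((-30 + 100.7) / 12.9) +
                                       exp((-30 - 56) / -23.1))),
               tolerance = 1e-12)
  # BK z time constant stays at its printed 1 (ms)
  expect_equal(gate_inf_tau("BK_s", "z", -60, 0.001)[["tau"]], 1)
})

test_that("Nernst potentials at 36 C reproduce the model's anchor values", {
  # soma E_K: NEURON-default K_i = 54.4 mM with K_o = 2 mM gives -88 mV
  expect_equal(round(nernst_potential(2, 54.4)), -88)
  # E_Na at the initial Na_i = 10 mM is just above the +70 mV floor
  expect_gt(nernst_potential(140, 10), 70)
  expect_equal(nernst_potential(2, 2), 0)
})
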