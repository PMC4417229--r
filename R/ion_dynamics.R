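#' Somatic Na+/K+ pump current
#'
#' Saturating pump with a fixed voltage dependence and a sharp exponential
#' dependence on intracellular Na+:
#' i = d_pump (V + 75) / \[(V + 80)(1 + exp(K_Na - \[Na\]i))\].
#' The denominator factor (V + 80) is guarded within 0.01 mV of its zero
#' (sign-preserving clamp), since V = -80 mV is transiently reachable.
#' The pump moves 3 Na+ out per 2 K+ in, so the Na+ and K+ component
#' currents are 3i and -2i and the net membrane current is +i
#' (hyperpolarizing when positive).
#'
#' @param v_mv membrane potential (mV).
#' @param na_i_mm intracellular Na+ (mM).
#' @param d_pump_ma_cm2 pump density (mA/cm2).
#' @param k_na_mm Na+ affinity constant (mM), default 40.
#' @return List with `i_pump`, `i_pump_na` (= 3i), `i_pump_k` (= -2i), all
#'   in uA/cm2.
#' @export
soma_pump <- function(v_mv, na_i_mm, d_pump_ma_cm2 = 1, k_na_mm = 40) {
  i <- .cpp_soma_pump(v_mv, na_i_mm, d_pump_ma_cm2, k_na_mm)
  list(i_pump = i, i_pump_na = 3 * i, i_pump_k = -2 * i)
}

#' Dendritic Na+/K+ pump current
#'
#' Hyperbolic saturation on extracellular K+:
#' i = d_pump / (1 + 2.245 / \[K+\]o), no voltage dependence, same
#' 3 Na+ : 2 K+ stoichiometry as the somatic pump.
#'
#' @param k_o_mm extracellular K+ (mM).
#' @param d_pump_ma_cm2 pump density (mA/cm2).
#' @return List with `i_pump`, `i_pump_na`, `i_pump_k` in uA/cm2.
#' @export
dendrite_pump <- function(k_o_mm, d_pump_ma_cm2 = 0.001) {
  if (k_o_mm <= 0) stop("k_o_mm must be positive")
  i <- .cpp_dend_pump(k_o_mm, d_pump_ma_cm2)
  list(i_pump = i, i_pump_na = 3 * i, i_pump_k = -2 * i)
}

#' Counterbalancing exchanger / pump current pair
#'
#' The Na+/Ca2+ exchanger admits 3 Na+ per extruded Ca2+ and is net
#' depolarizing: I_ex_net = -g_ex.  The paired Na+/K+ pump is net
#' hyperpolarizing: I_pump_net = +g_pump.  At the soma the pair is slightly
#' mismatched (g_ex = g_pump + 0.011 mA/cm2), producing a small constant
#' net Na+ influx; at the dendrite the pair cancels exactly.  Component
#' Na+/Ca2+/K+ fluxes are reported for the Na+ and K+ book-keeping.
#'
#' @param set a [pump_exchanger_set()].
#' @param compartment `"soma"` or `"dendrite"`.
#' @return List with net currents `i_ex_net`, `i_pump_net` and components
#'   `i_ex_na`, `i_ex_ca`, `i_pump_na`, `i_pump_k`, all in uA/cm2.
#' @export
counterbalance_currents <- function(set = pump_exchanger_set(),
                                    compartment = c("soma", "dendrite")) {
  compartment <- match.arg(compartment)
  g_ex <- 1000 * if (compartment == "soma") set$g_ex_s else set$g_ex_d
  g_pump <- 1000 * if (compartment == "soma") set$g_pump_s else set$g_pump_d
  list(i_ex_net = -g_ex, i_pump_net = +g_pump,
       i_ex_na = -3 * g_ex, i_ex_ca = +2 * g_ex,
       i_pump_na = +3 * g_pump, i_pump_k = -2 * g_pump)
}

#' Advance somatic shell Ca2+ one step
#'
#' Explicit Euler update of
#' d\[Ca\]/dt = -(1e4) I_Ca\[mA/cm2\] / (2 F depth) - beta \[Ca\],
#' followed by the 100 nM floor clamp.  `i_ca_uA` is the somatic Ca2+
#' current density (uA/cm2, inward negative).
#'
#' @param ca_mm shell Ca2+ (mM).
#' @param i_ca_uA Ca2+ current density (uA/cm2).
#' @param dt_ms time step (ms).
#' @param depth_um shell depth (um), default 0.1.
#' @param beta diffusion rate constant (1/ms), default 1.
#' @return Updated Ca2+ (mM), never below 1e-4.
#' @export
step_soma_ca <- function(ca_mm, i_ca_uA, dt_ms, depth_um = 0.1, beta = 1) {
  .cpp_step_soma_ca(ca_mm, i_ca_uA, dt_ms, depth_um, beta)
}

#' Advance dendritic shell Ca2+ one step
#'
#' Explicit Euler update of
#' d\[Ca\]/dt = chan - kt \[Ca\]/(\[Ca\] + kd) + (y - \[Ca\])/tau_r with
#' chan = -(1e4) I_Ca\[mA/cm2\] / (2 F depth) rectified at zero (outward
#' Ca2+ current does not deplete the shell).  The shell depth carries the
#' dendritic correction factor.
#'
#' @param ca_mm shell Ca2+ (mM).
#' @param i_ca_uA total dendritic Ca2+ current density (uA/cm2).
#' @param dt_ms time step (ms).
#' @param depth_um shell depth (um); default 0.1 * 6.16 (cd applied).
#' @param kt,kd,tau_r,y pump and relaxation constants (mM/ms, mM, ms, mM).
#' @return Updated Ca2+ (mM).
#' @export
step_dend_ca <- function(ca_mm, i_ca_uA, dt_ms, depth_um = 0.616,
                         kt = 4e-5, kd = 4e-5, tau_r = 2, y = 4e-5) {
  .cpp_step_dend_ca(ca_mm, i_ca_uA, dt_ms, depth_um, kt, kd, tau_r, y)
}

#' Advance intracellular Na+ one step from the delayed net current
#'
#' d\[Na\]i/dt = (4e4 / (F d)) I_net\[mA/cm2\] where d is the somatic
#' diameter (um) and `i_net_uA` the tau-delayed net Na+ influx (positive =
#' influx surplus) in uA/cm2.  Applies the 10 mM floor, then recomputes
#' E_Na by the Nernst relation and applies its +70 mV floor.
#'
#' @param na_i_mm intracellular Na+ (mM).
#' @param i_net_uA delayed net Na+ influx (uA/cm2).
#' @param dt_ms time step (ms).
#' @param soma_diam_um somatic diameter (um).
#' @param na_o_mm extracellular Na+ (mM), default 140.
#' @return List with `na_i` (mM) and `e_na` (mV).
#' @export
step_na_i <- function(na_i_mm, i_net_uA, dt_ms, soma_diam_um = 22,
                      na_o_mm = 140) {
  k <- 40 / (.FARADAY * soma_diam_um)   # mM/ms per uA/cm2
  na <- max(na_i_mm + dt_ms * k * i_net_uA, 10)
  e_na <- max(nernst_potential(na_o_mm, na), 70)
  list(na_i = na, e_na = e_na)
}

#' Advance extracellular K+ one step
#'
#' d\[K\]o/dt = Q (I_K_out - I_K_in) / (F wid), then clamped to the
#' \[2, 3.03\] mM band.  `i_k_out_uA` sums the seven gated dendritic K+
#' currents; `i_k_in_uA` sums the two pump K+ uptake terms (positive
#' magnitudes).
#'
#' @param k_o_mm extracellular K+ (mM).
#' @param i_k_out_uA gated K+ efflux (uA/cm2).
#' @param i_k_in_uA pump K+ uptake (uA/cm2).
#' @param dt_ms time step (ms).
#' @param q accumulation factor (default 0.0119, the re-tuned value for
#'   the two-compartment model at Ra = 35.4 Ohm cm).
#' @param wid_um extracellular shell thickness (um).
#' @param ko_min,ko_max clamp band (mM).
#' @return Updated K+ (mM) within the clamp band.
#' @export
step_k_o <- function(k_o_mm, i_k_out_uA, i_k_in_uA, dt_ms, q = 0.0119,
                     wid_um = 0.07, ko_min = 2, ko_max = 3.03) {
  .cpp_step_k_o(k_o_mm, i_k_out_uA, i_k_in_uA, dt_ms, q, wid_um,
                ko_min, ko_max)
}

#' Fixed-capacity delay line (first-in-first-out)
#'
#' Passes a sampled signal through the same zero-pre-filled ring buffer
#' used for the 5-s Na+ current lag in the simulation core: the output at
#' sample t is the input at sample t - tau (zero for t < tau).
#'
#' @param x numeric input series sampled at `dt_ms`.
#' @param tau_ms delay (ms).
#' @param dt_ms sampling step (ms).
#' @return Delayed series of the same length.
#' @export
na_delay_line <- function(x, tau_ms, dt_ms) {
  .cpp_delay_line(as.numeric(x), tau_ms, dt_ms)
}
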