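#' Gate steady state and time constant
#'
#' Evaluates the steady-state value and time constant (ms) of one
#' Hodgkin-Huxley gate of a membrane current at voltage `v_mv` (and, for
#' the Ca2+-gated BK/SK/K2 z gates, shell Ca2+ concentration `ca_mm`).
#' Somatic time constants are tabulated in seconds in the source
#' descriptions and are returned converted to ms; dendritic rate constants
#' are per-ms with their temperature factors applied.
#'
#' Current ids: soma `"K_fast"`, `"K_mid"`, `"K_slow"`, `"CaP_s"`,
#' `"Ih_s"`, `"BK_s"`, `"SK"`; dendrite `"CaT"`, `"CaE"`, `"CaP_d"`,
#' `"Ih_d"`, `"Kv12"`, `"KA"`, `"KM"`, `"KD"`, `"DR"`, `"BK_d"`, `"K2"`,
#' `"ERG"`.  Gate ids: `"m"`, `"h"`, `"z"`.  The SK z gate is an
#' instantaneous function of Ca2+ (tau reported as 0).
#'
#' @param current_id,gate_id current and gate name (see above).
#' @param v_mv membrane potential (mV).
#' @param ca_mm shell Ca2+ concentration (mM); required for the z gates.
#' @param literal_sigmoid audit mode: reproduce the printed `1/exp(...)`
#'   sigmoid form for the somatic voltage gates instead of the Boltzmann
#'   `1/(1+exp(...))` reading (the printed form exceeds 1 above the
#'   half-activation voltage and is not used for simulation).
#' @param erg_vhalf half-activation voltage of the ERG m gate (mV).
#' @return Named numeric vector `c(inf = , tau = )`, tau in ms.
#' @examples
#' gate_inf_tau("BK_s", "z", v_mv = -60, ca_mm = 0.001)  # inf = 0.5
#' @export
gate_inf_tau <- function(current_id, gate_id, v_mv, ca_mm = NA_real_,
                         literal_sigmoid = FALSE, erg_vhalf = -5) {
  stopifnot(is.finite(v_mv))
  .cpp_gate_inf_tau(current_id, gate_id, v_mv, ca_mm, literal_sigmoid,
                    erg_vhalf)
}

#' Voltage-dependent rate set of the resurgent Na+ Markov scheme
#'
#' The 13-state scheme (closed C1-C5, open O, open-blocked OB, inactivated
#' I1-I6) uses activation rate alpha = 150 exp(V/20), deactivation rate
#' beta = 3 exp(-V/20), fixed open/closed transition rates gamma = 150,
#' delta = 40, inactivation on/off rates Con, Coff, Oon, Ooff, allosteric
#' factors a = (Oon/Con)^(1/4), b = (Ooff/Coff)^(1/4), block rate
#' eps = 1.75 and unblock rate zeta = 0.03 exp(-V/25).  All rates per ms.
#'
#' @param v_mv membrane potential (mV).
#' @return Named numeric vector of the twelve rate constants.
#' @export
markov_rates <- function(v_mv) {
  stopifnot(is.finite(v_mv))
  .cpp_markov_rates(v_mv)
}

#' Generator matrix of the Markov resurgent Na+ scheme
#'
#' Returns the 13 x 13 transition-rate (generator) matrix M at clamped
#' voltage `v_mv`, such that d x / dt = M x for the occupancy vector x.
#' Columns sum to zero.
#'
#' @param v_mv membrane potential (mV).
#' @return 13 x 13 matrix with state dimnames.
#' @export
markov_qmatrix <- function(v_mv) {
  .cpp_markov_qmatrix(v_mv)
}

#' Advance the Markov occupancy vector one time step
#'
#' Backward-Euler update of the 13-state occupancy vector at clamped
#' voltage, with renormalization so the occupancies remain a probability
#' vector (sum 1) to machine precision.
#'
#' @param state occupancy vector of length 13 (order C1-C5, O, OB, I1-I6).
#' @param v_mv membrane potential (mV).
#' @param dt_ms time step (ms); `dt_ms = 0` returns the state unchanged.
#' @return Updated occupancy vector.
#' @export
markov_step <- function(state, v_mv, dt_ms) {
  .cpp_markov_step(as.numeric(state), v_mv, dt_ms)
}

#' Steady-state occupancy of the Markov scheme at clamped voltage
#'
#' Solves M x = 0 with sum(x) = 1 for the generator M of
#' [markov_qmatrix()] (least-squares on the augmented system).
#'
#' @param v_mv membrane potential (mV).
#' @return Occupancy vector of length 13 summing to 1.
#' @export
markov_steady <- function(v_mv) {
  M <- markov_qmatrix(v_mv)
  A <- rbind(M, rep(1, ncol(M)))
  b <- c(rep(0, nrow(M)), 1)
  x <- qr.solve(A, b)
  x[x < 0] <- 0
  x <- x / sum(x)
  names(x) <- colnames(M)
  x
}

#' Goldman-Hodgkin-Katz Ca2+ flux term
#'
#' GHK current-voltage relation for the somatic P-type Ca2+ current, with
#' fixed concentrations [Ca2+]i = 100 nM and [Ca2+]o = 2 mM (this term
#' does not see the dynamic shell Ca2+), T = 295 K and permeability
#' `perm_cm_s` (default 5e-5 cm/s).  The removable singularity at V = 0 is
#' handled by the analytic limit 2 P F ([Ca]i - [Ca]o).
#'
#' @param v_mv membrane potential (mV).
#' @param perm_cm_s Ca2+ permeability (cm/s).
#' @return Flux in mA/cm2 (negative = inward).
#' @export
ghk_flux <- function(v_mv, perm_cm_s = 5e-5) {
  stopifnot(is.finite(v_mv))
  .cpp_ghk_flux(v_mv, perm_cm_s)
}

# gate composition (exponents) per current; NaR and CaP_s handled apart
.gate_composition <- list(
  K_fast = c(m = 3, h = 1), K_mid = c(m = 4), K_slow = c(m = 4),
  Ih_s = c(m = 1), BK_s = c(m = 3, z = 2, h = 1), SK = c(z = 1),
  Leak_s = numeric(0),
  CaT = c(m = 1, h = 1), CaE = c(m = 1, h = 1), CaP_d = c(m = 1),
  Ih_d = c(m = 1), Kv12 = c(m = 4), KA = c(m = 4, h = 1), KM = c(m = 1),
  KD = c(m = 1, h = 1), DR = c(m = 4), BK_d = c(m = 1, z = 2),
  K2 = c(m = 1, z = 2), ERG = c(m = 1, h = 1), Leak_d = numeric(0),
  NaR = c(O = 1))

#' Instantaneous current density of one mechanism
#'
#' Evaluates I = g_max * (product of gates^exponents) * (V - E) in uA/cm2
#' (outward positive) for the ohmic mechanisms, I = g_max * m * ghk(V) for
#' the GHK-based somatic P-type Ca2+ current (`"CaP_s"`), and
#' I = g_max * O * (V - E_Na) for the Markov resurgent Na+ current
#' (`"NaR"`, gate named `O`).
#'
#' @param current_id mechanism id (see [gate_inf_tau()]; additionally
#'   `"Leak_s"`, `"Leak_d"`, `"NaR"`, `"CaP_s"`).
#' @param gates named vector of gate values in \[0, 1\] (names `m`, `h`,
#'   `z`, or `O` for NaR); missing required gates are an error.
#' @param g_max maximal conductance density (mS/cm2).
#' @param v_mv membrane potential (mV).
#' @param e_rev_mv reversal potential (mV); ignored for `"CaP_s"`.
#' @param perm_cm_s GHK permeability for `"CaP_s"` (cm/s).
#' @return Current density in uA/cm2, positive outward.
#' @examples
#' eval_current("Leak_s", numeric(0), g_max = 0.1, v_mv = -60,
#'              e_rev_mv = -70)  # +1 uA/cm2
#' @export
eval_current <- function(current_id, gates, g_max, v_mv, e_rev_mv = NA,
                         perm_cm_s = 5e-5) {
  comp <- .gate_composition[[current_id]]
  if (is.null(comp) && current_id != "CaP_s")
    stop("unknown current id '", current_id, "'")
  if (g_max < 0) stop("g_max must be non-negative")
  if (current_id == "CaP_s") {
    if (!"m" %in% names(gates)) stop("CaP_s requires gate 'm'")
    return(g_max * unname(gates["m"]) * 1000 * ghk_flux(v_mv, perm_cm_s))
  }
  missing <- setdiff(names(comp), names(gates))
  if (length(missing))
    stop("missing gate value(s) for ", current_id, ": ",
         paste(missing, collapse = ", "))
  gp <- prod(gates[names(comp)]^comp)
  if (length(comp) && (any(gates[names(comp)] < 0) ||
                       any(gates[names(comp)] > 1)))
    stop("gate values must lie in [0, 1]")
  if (!is.finite(e_rev_mv)) stop("e_rev_mv required for ohmic currents")
  g_max * gp * (v_mv - e_rev_mv)
}

#' Nernst reversal potential at 36 C
#'
#' @param conc_out,conc_in outer and inner concentrations (mM).
#' @param z ionic valence.
#' @return Potential in mV.
#' @export
nernst_potential <- function(conc_out, conc_in, z = 1) {
  (.RTF_MV / z) * log(conc_out / conc_in)
}
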