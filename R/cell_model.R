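#' Axial (electrotonic) currents between the compartments
#'
#' The coupling resistance is R = Ra(L_s/2)/(pi r_s^2) +
#' Ra(L_d/2)/(pi r_d^2) (identical in both directions).  `i_ds` is the
#' absolute current into the soma, (V_d - V_s)/R, and `i_sd` the current
#' into the dendrite, (V_s - V_d)/R; they are equal and opposite.  Inside
#' the membrane equations each is divided by the receiving compartment's
#' membrane area to join the density-based current balance.
#'
#' @param v_soma_mv,v_dend_mv compartment voltages (mV).
#' @param cell a [purkinje_cell()] (geometry source).
#' @return List with `i_ds_nA`, `i_sd_nA` (nA), the coupling resistance
#'   `r_Mohm`, and the density equivalents `i_ds_uA_cm2`, `i_sd_uA_cm2`
#'   (uA/cm2, referred to soma and dendrite areas respectively).
#' @export
axial_currents <- function(v_soma_mv, v_dend_mv, cell = purkinje_cell()) {
  g <- cell$geometry
  r <- g$r_coupling_Mohm
  i_ds <- (v_dend_mv - v_soma_mv) / r      # mV / MOhm = nA
  i_sd <- -i_ds
  list(i_ds_nA = i_ds, i_sd_nA = i_sd, r_Mohm = r,
       i_ds_uA_cm2 = i_ds * 1e-3 / (g$area_soma_um2 * 1e-8),
       i_sd_uA_cm2 = i_sd * 1e-3 / (g$area_dend_um2 * 1e-8))
}

# full initial state: voltages and ions from the cell, every gate at its
# steady state at the initial voltage, Markov chain at its stationary
# distribution
.initial_state <- function(cell) {
  p <- cell$params
  vs <- cell$init$v_soma; vd <- cell$init$v_dend
  cas <- cell$init$ca_soma; cad <- cell$init$ca_dend
  lit <- isTRUE(p$literal_sigmoid)
  gi <- function(cur, gate, v, ca = NA_real_)
    unname(gate_inf_tau(cur, gate, v, ca, lit, p$erg_vhalf)["inf"])
  gates <- c(
    kfast_m = gi("K_fast", "m", vs), kfast_h = gi("K_fast", "h", vs),
    kmid_m = gi("K_mid", "m", vs), kslow_m = gi("K_slow", "m", vs),
    caps_m = gi("CaP_s", "m", vs), ihs_m = gi("Ih_s", "m", vs),
    bks_m = gi("BK_s", "m", vs), bks_h = gi("BK_s", "h", vs),
    bks_z = gi("BK_s", "z", vs, cas),
    cat_m = gi("CaT", "m", vd), cat_h = gi("CaT", "h", vd),
    cae_m = gi("CaE", "m", vd), cae_h = gi("CaE", "h", vd),
    capd_m = gi("CaP_d", "m", vd), ihd_m = gi("Ih_d", "m", vd),
    kv12_m = gi("Kv12", "m", vd),
    ka_m = gi("KA", "m", vd), ka_h = gi("KA", "h", vd),
    km_m = gi("KM", "m", vd),
    kd_m = gi("KD", "m", vd), kd_h = gi("KD", "h", vd),
    dr_m = gi("DR", "m", vd),
    bkd_m = gi("BK_d", "m", vd), bkd_z = gi("BK_d", "z", vd, cad),
    k2_m = gi("K2", "m", vd), k2_z = gi("K2", "z", vd, cad),
    erg_m = gi("ERG", "m", vd), erg_h = gi("ERG", "h", vd))
  stopifnot(identical(names(gates), as.character(.cpp_gate_names())))
  list(v_soma = vs, v_dend = vd, gates = gates,
       markov = unname(markov_steady(vs)),
       ca_soma = cas, ca_dend = cad,
       na_i = cell$init$na_i, k_o = cell$init$k_o)
}

#' Simulate the two-compartment model
#'
#' Fixed-step integration (default 25 us) of the full model: both membrane
#' equations (linearized implicit voltage update with axial coupling), all
#' Hodgkin-Huxley gates (exponential relaxation), the 13-state Markov
#' resurgent Na+ chain (backward Euler with renormalization), the Ca2+,
#' Na+ and extracellular K+ pools with their hard clamps, and the 5-s
#' delayed Na+ feedback onto the somatic pump.  The simulation is fully
#' deterministic: identical configurations give identical traces.
#'
#' @param cell a [purkinje_cell()] (possibly transformed by the protocol
#'   helpers [set_kna()], [bk_knockout()], [add_erg()],
#'   [alcohol_protocol()]).
#' @param duration_s simulated time (s); `0` returns the initial sample
#'   only.
#' @param dt_ms integration step (ms), default 0.025 (25 us).
#' @param stride record every `stride`-th step (default 20, i.e. 0.5 ms
#'   sampling).
#' @param record_ions also record Ca2+/Na+/K+ pools, reversal potentials
#'   and the Markov open-state occupancy.
#' @param init optional full initial state (as returned in the
#'   `final_state` attribute of a previous trace) to continue a run.
#' @return A data.frame of class `purkinje_trace` with columns `t_ms`,
#'   `v_soma`, `v_dend` and, if `record_ions`, `ca_soma`, `ca_dend`,
#'   `na_i`, `k_o`, `e_na`, `e_k_dend`, `o_nar`.  Attributes: `dt_ms`,
#'   `stride`, `final_state`, `cell`.
#' @examples
#' \donttest{
#' cell <- purkinje_cell()
#' tr <- simulate_cell(cell, duration_s = 1)
#' summary(tr)
#' }
#' @export
simulate_cell <- function(cell, duration_s, dt_ms = 0.025, stride = 20L,
                          record_ions = TRUE, init = NULL) {
  stopifnot(inherits(cell, "purkinje_cell"), duration_s >= 0, dt_ms > 0)
  if (is.null(init)) init <- .initial_state(cell)
  raw <- .cpp_simulate(cell$params, init, dt_ms, duration_s * 1000,
                       as.integer(stride), record_ions)
  fin <- raw$final_state
  raw$final_state <- NULL
  tr <- as.data.frame(raw)
  attr(tr, "dt_ms") <- dt_ms
  attr(tr, "stride") <- as.integer(stride)
  attr(tr, "final_state") <- fin
  attr(tr, "cell") <- cell
  class(tr) <- c("purkinje_trace", "data.frame")
  tr
}

#' @export
print.purkinje_trace <- function(x, ...) {
  dur <- utils::tail(x$t_ms, 1) / 1000
  cat(sprintf("purkinje_trace: %.4g s at %.4g ms sampling (%d samples)\n",
              dur, attr(x, "dt_ms") * attr(x, "stride"), nrow(x)))
  cat(sprintf("  V_soma range [%.1f, %.1f] mV; V_dend range [%.1f, %.1f] mV\n",
              min(x$v_soma), max(x$v_soma), min(x$v_dend), max(x$v_dend)))
  invisible(x)
}

#' @export
summary.purkinje_trace <- function(object, threshold_mv = -20, ...) {
  sp <- detect_spikes(object, threshold_mv = threshold_mv)
  segs <- classify_activity(object)
  out <- list(
    duration_s = utils::tail(object$t_ms, 1) / 1000,
    n_spikes_soma = length(sp),
    mean_rate_hz = if (length(sp) > 1)
      1000 * (length(sp) - 1) / diff(range(sp)) else 0,
    states = table(segs$label),
    trimodal_period_s = trimodal_period(segs))
  class(out) <- "summary.purkinje_trace"
  out
}

#' @export
print.summary.purkinje_trace <- function(x, ...) {
  cat(sprintf("%.4g s simulated; %d somatic spikes (mean rate %.1f Hz)\n",
              x$duration_s, x$n_spikes_soma, x$mean_rate_hz))
  cat("activity segments:\n")
  print(x$states)
  if (is.na(x$trimodal_period_s))
    cat("trimodal period: undetermined (no complete cycle)\n")
  else
    cat(sprintf("trimodal period: %.2f s\n", x$trimodal_period_s))
  invisible(x)
}

#' @export
plot.purkinje_trace <- function(x, which = c("both", "soma", "dendrite"),
                                ...) {
  which <- match.arg(which)
  t_s <- x$t_ms / 1000
  if (which == "both") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(t_s, x$v_soma, type = "l", xlab = "time (s)",
                   ylab = "V_soma (mV)", ...)
    graphics::plot(t_s, x$v_dend, type = "l", xlab = "time (s)",
                   ylab = "V_dend (mV)", ...)
  } else {
    v <- if (which == "soma") x$v_soma else x$v_dend
    graphics::plot(t_s, v, type = "l", xlab = "time (s)",
                   ylab = sprintf("V_%s (mV)", which), ...)
  }
  invisible(x)
}
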