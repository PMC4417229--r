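#' Pump densities under the progressing pump-block (alcohol) ramp
#'
#' An increasing fraction of blocked Na+/K+ pump molecules is emulated by
#' ramping the four pump densities down in time: the somatic saturating
#' pump from t = 0 at rate Y, and the dendritic saturating pump plus both
#' counterbalance pump densities from t = 50 s at rate M (evaluated as
#' base - M t, per the printed law).  All densities are floored at zero;
#' the exchanger densities are untouched.
#'
#' @param t_s protocol time (s), >= 0.
#' @param base a [pump_exchanger_set()] of pre-ramp densities.
#' @param y_ma_cm2_s somatic saturating-pump ramp rate (mA/cm2/s).
#' @param m_ma_cm2_s late ramp rate for the other three densities.
#' @param onset_s onset of the late ramps (s).
#' @return A [pump_exchanger_set()] with the ramped densities.
#' @examples
#' alcohol_ramp(50)$d_pump_s  # 1 - 0.014 * 50 = 0.3
#' @export
alcohol_ramp <- function(t_s, base = pump_exchanger_set(),
                         y_ma_cm2_s = 0.014, m_ma_cm2_s = 0.005,
                         onset_s = 50) {
  stopifnot(t_s >= 0)
  d_pump_s <- max(base$d_pump_s - y_ma_cm2_s * t_s, 0)
  late <- t_s > onset_s
  d_pump_d <- if (late) max(base$d_pump_d - m_ma_cm2_s * t_s, 0)
              else base$d_pump_d
  g_pump_s <- if (late) max(base$g_pump_s - m_ma_cm2_s * t_s, 0)
              else base$g_pump_s
  g_pump_d <- if (late) max(base$g_pump_d - m_ma_cm2_s * t_s, 0)
              else base$g_pump_d
  pump_exchanger_set(d_pump_s = d_pump_s, d_pump_d = d_pump_d,
                     g_ex_s = base$g_ex_s, g_pump_s = g_pump_s,
                     g_ex_d = base$g_ex_d, g_pump_d = g_pump_d,
                     k_na = base$k_na)
}

#' Activate the pump-block (alcohol) protocol on a cell
#'
#' Marks the cell so that [simulate_cell()] evaluates the ramps of
#' [alcohol_ramp()] at every integration step.  By default the cell is
#' also set to the K_Na = 12 mM condition, whose pre-ramp state is
#' quiescent, matching the protocol's published starting point.
#'
#' @param cell a [purkinje_cell()].
#' @param k_na Na+ affinity constant during the protocol (mM).
#' @param y_ma_cm2_s,m_ma_cm2_s,onset_s ramp parameters (see
#'   [alcohol_ramp()]).
#' @return The transformed cell.
#' @export
alcohol_protocol <- function(cell, k_na = 12, y_ma_cm2_s = 0.014,
                             m_ma_cm2_s = 0.005, onset_s = 50) {
  stopifnot(inherits(cell, "purkinje_cell"))
  cell$params$alcohol <- TRUE
  cell$params$alc_y <- y_ma_cm2_s
  cell$params$alc_m <- m_ma_cm2_s
  cell$params$alc_onset_s <- onset_s
  cell$params$k_na <- k_na
  cell
}

#' Set the somatic pump's Na+ affinity constant
#'
#' K_Na = 40 mM is the default (trimodal) condition; lowering it to 12 mM
#' (still physiological) activates the pump at resting Na+ levels and
#' switches the model into quiescence.
#'
#' @param cell a [purkinje_cell()].
#' @param value_mm new K_Na (mM), > 0.
#' @return The transformed cell.
#' @export
set_kna <- function(cell, value_mm) {
  stopifnot(inherits(cell, "purkinje_cell"))
  if (!is.finite(value_mm) || value_mm <= 0)
    stop("K_Na must be positive")
  cell$params$k_na <- value_mm
  cell
}

#' BK channel knockout
#'
#' Sets the BK maximal conductance to zero in both compartments (emulating
#' a genetic knockout); every other parameter is untouched.  Without BK
#' the dendritic Ca2+ spikes cannot repolarize and both compartments lock
#' into depolarization block at distinct potentials.
#'
#' @param cell a [purkinje_cell()].
#' @return The transformed cell (idempotent).
#' @export
bk_knockout <- function(cell) {
  stopifnot(inherits(cell, "purkinje_cell"))
  cell$params$g_bk_s <- 0
  cell$params$g_bk_d <- 0
  cell
}

#' Insert a dendritic ERG K+ current
#'
#' Adds the ERG (ether-a-go-go-related gene) K+ current to the dendrite
#' compartment, with the m-gate half-activation at -5 mV (appropriate for
#' physiological external Ca2+).  The default density is 0.5 * C_d mS/cm2,
#' the value at which ERG restores dendritic spike repolarization in the
#' absence of BK.
#'
#' @param cell a [purkinje_cell()].
#' @param gmax_ms_cm2 maximal conductance (mS/cm2); `0` de-inserts.
#' @return The transformed cell.
#' @export
add_erg <- function(cell, gmax_ms_cm2 = 0.5 * cell$cd) {
  stopifnot(inherits(cell, "purkinje_cell"))
  if (!is.finite(gmax_ms_cm2) || gmax_ms_cm2 < 0)
    stop("gmax_ms_cm2 must be non-negative")
  cell$params$g_erg <- gmax_ms_cm2
  cell
}
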