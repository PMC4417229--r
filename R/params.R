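#' Maximal conductance table
#'
#' Default maximal conductance densities (mS/cm2) for every membrane
#' current: the somatic values, the dendritic values of the full
#' 1089-compartment model, and the dendritic values of the two-compartment
#' model, which are the full-model values multiplied by the dendritic
#' correction factor `cd`.
#'
#' @param cd dendritic correction factor applied to the two-compartment
#'   dendritic column (default 6.16, the published surface-area ratio).
#' @return A data.frame with columns `current`, `soma`, `dend_full` and
#'   `dend_reduced` (= `dend_full * cd`).
#' @export
table1_conductances <- function(cd = 6.16) {
  tab <- data.frame(
    current = c("NaR", "CaP", "CaT", "CaE", "KA", "KD", "KM", "DR", "BK",
                "SK", "K2", "Kv12", "K_fast", "K_mid", "K_slow", "Ih",
                "Leak"),
    soma = c(156, 0.5, 0, 0, 0, 0, 0, 0, 72.86,
             10, 0, 0, 41.6, 20.8, 41.6, 1.04, 0.1),
    dend_full = c(0, 1.6, 0.6, 3.2, 32, 36, 0.004, 0.24, 60,
                  0, 0.16, 1, 0, 0, 0, 0.29, 0.000079),
    stringsAsFactors = FALSE)
  tab$dend_reduced <- tab$dend_full * cd
  tab
}

#' Default Na+/K+ pump and Na+/Ca2+ exchanger densities
#'
#' The soma carries a saturating pump (density `d_pump_s`, voltage- and
#' Na+-dependent) plus a constant exchanger/pump counterbalance pair
#' (`g_ex_s`, `g_pump_s`); the dendrite carries the analogous set.  All
#' densities are in mA/cm2.  The somatic pair is deliberately mismatched
#' (`g_ex_s = g_pump_s + 0.011`), permitting a small net Na+ influx; the
#' dendritic pair cancels exactly.  `k_na` (mM) is the pump's Na+ affinity
#' constant.
#'
#' @param d_pump_s,d_pump_d saturating pump densities (mA/cm2).
#' @param g_ex_s,g_pump_s,g_ex_d,g_pump_d counterbalance densities (mA/cm2).
#' @param k_na Na+ affinity constant of the somatic pump (mM).
#' @return A list of class `pump_exchanger_set`.
#' @export
pump_exchanger_set <- function(d_pump_s = 1, d_pump_d = 0.001,
                               g_ex_s = 0.511, g_pump_s = 0.5,
                               g_ex_d = 0.0021, g_pump_d = 0.0021,
                               k_na = 40) {
  vals <- c(d_pump_s = d_pump_s, d_pump_d = d_pump_d, g_ex_s = g_ex_s,
            g_pump_s = g_pump_s, g_ex_d = g_ex_d, g_pump_d = g_pump_d,
            k_na = k_na)
  if (any(vals < 0)) stop("pump/exchanger densities must be non-negative")
  structure(as.list(vals), class = "pump_exchanger_set")
}

# flat default parameter list for a given cd; dendritic conductances carry cd
.default_params <- function(cd = 6.16) {
  tab <- table1_conductances(cd)
  g <- function(cur, col) tab[tab$current == cur, col]
  pumps <- pump_exchanger_set()
  list(
    # soma conductances (mS/cm2)
    g_nar = g("NaR", "soma"), g_kfast = g("K_fast", "soma"),
    g_kmid = g("K_mid", "soma"), g_kslow = g("K_slow", "soma"),
    g_cap_s = g("CaP", "soma"), g_ih_s = g("Ih", "soma"),
    g_bk_s = g("BK", "soma"), g_sk = g("SK", "soma"),
    g_leak_s = g("Leak", "soma"),
    # dendrite conductances (mS/cm2, cd applied)
    g_cat = g("CaT", "dend_reduced"), g_cae = g("CaE", "dend_reduced"),
    g_cap_d = g("CaP", "dend_reduced"), g_ih_d = g("Ih", "dend_reduced"),
    g_kv12 = g("Kv12", "dend_reduced"), g_ka = g("KA", "dend_reduced"),
    g_km = g("KM", "dend_reduced"), g_kd = g("KD", "dend_reduced"),
    g_dr = g("DR", "dend_reduced"), g_bk_d = g("BK", "dend_reduced"),
    g_k2 = g("K2", "dend_reduced"), g_leak_d = g("Leak", "dend_reduced"),
    g_erg = 0, erg_vhalf = -5,
    ghk_perm = 5e-5,
    # reversal potentials (mV)
    e_k_soma = -88, e_leak_s = -70, e_h_s = -30,
    e_ca_d = 135, e_leak_d = -80, e_h_d = -32.9,
    na_o = 140, k_i = .K_IN_MM,
    # capacitance (uF/cm2); dendritic value carries cd
    cm_s = 0.8, cm_d = 0.8 * cd,
    # pumps/exchangers (mA/cm2)
    d_pump_s = pumps$d_pump_s, d_pump_d = pumps$d_pump_d,
    g_ex_s = pumps$g_ex_s, g_pump_s = pumps$g_pump_s,
    g_ex_d = pumps$g_ex_d, g_pump_d = pumps$g_pump_d,
    k_na = pumps$k_na,
    # Ca2+ shells; dendritic depth carries cd
    depth_s = 0.1, beta_ca_s = 1,
    depth_d = 0.1 * cd, ca_kt = 4e-5, ca_kd = 4e-5, ca_tau_r = 2,
    ca_y = 4e-5,
    # Na+ feedback lag (s) and extracellular K+ shell
    tau_na_s = 5,
    k_acc_q = 0.0119, k_wid = 0.07, ko_min = 2, ko_max = 3.03,
    # protocol defaults (inactive)
    alcohol = FALSE, alc_y = 0.014, alc_m = 0.005, alc_onset_s = 50,
    literal_sigmoid = FALSE)
}

#' Construct a two-compartment Purkinje cell model
#'
#' Assembles the full parameter set of the reduced Purkinje neuron: a
#' cylindrical soma (22 x 22 um) and an equivalent-cylinder dendrite
#' (default 529.29 um long, 3.22 um diameter), coupled by an axial
#' resistance computed from the specific axial resistivity `ra_ohm_cm`.
#' Dendritic conductance densities, dendritic membrane capacitance and the
#' dendritic Ca2+ shell depth are the full-model values scaled by the
#' dendritic correction factor `cd`.
#'
#' Any model parameter can be overridden by name through `...` (overrides
#' act on the final, cd-scaled values), e.g. `purkinje_cell(k_na = 12)`.
#'
#' @param cd dendritic correction factor (surface-area ratio of the
#'   original arbour to its equivalent cylinder).
#' @param dend_length_um,dend_diam_um dendrite compartment dimensions (um).
#' @param soma_length_um,soma_diam_um soma dimensions (um).
#' @param ra_ohm_cm specific axial resistivity (Ohm cm).
#' @param ... named parameter overrides (see [table1_conductances()] and
#'   [pump_exchanger_set()] for the main names).
#' @return An object of class `purkinje_cell`: a list with elements
#'   `params` (flat parameter list), `geometry`, `init` (initial state) and
#'   `cd`.
#' @examples
#' cell <- purkinje_cell()
#' cell$geometry$r_coupling_Mohm
#' @export
purkinje_cell <- function(cd = 6.16,
                          dend_length_um = 529.29, dend_diam_um = 3.22,
                          soma_length_um = 22, soma_diam_um = 22,
                          ra_ohm_cm = 35.4, ...) {
  p <- .default_params(cd)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    gpar <- grepl("^(g_|d_pump|cm_)", names(dots))
    bad <- unlist(dots[gpar]) < 0
    if (any(bad))
      stop("negative density not allowed: ",
           paste(names(dots)[gpar][bad], collapse = ", "))
    p[names(dots)] <- dots
  }

  area_s <- pi * soma_diam_um * soma_length_um          # lateral, um2
  area_d <- pi * dend_diam_um * dend_length_um
  rc <- axial_resistance(soma_length_um, soma_diam_um / 2,
                         dend_length_um, dend_diam_um / 2, ra_ohm_cm)

  geometry <- list(
    soma_length_um = soma_length_um, soma_diam_um = soma_diam_um,
    dend_length_um = dend_length_um, dend_diam_um = dend_diam_um,
    ra_ohm_cm = ra_ohm_cm,
    area_soma_um2 = area_s, area_dend_um2 = area_d,
    r_coupling_Mohm = rc)

  p$area_s_cm2 <- area_s * 1e-8
  p$area_d_cm2 <- area_d * 1e-8
  p$r_coupling_Mohm <- rc
  p$soma_diam_um <- soma_diam_um

  init <- list(v_soma = -65, v_dend = -65,
               ca_soma = 5e-5, ca_dend = 4e-5,
               na_i = 10, k_o = 2)

  structure(list(params = p, geometry = geometry, init = init, cd = cd),
            class = "purkinje_cell")
}

#' @export
print.purkinje_cell <- function(x, ...) {
  g <- x$geometry
  cat("Two-compartment Purkinje neuron model\n")
  cat(sprintf("  soma:     %.4g x %.4g um cylinder (%.0f um2 lateral)\n",
              g$soma_length_um, g$soma_diam_um, g$area_soma_um2))
  cat(sprintf("  dendrite: %.4g x %.4g um cylinder (%.0f um2 lateral)\n",
              g$dend_length_um, g$dend_diam_um, g$area_dend_um2))
  cat(sprintf("  Ra = %.4g Ohm cm, coupling R = %.4g MOhm, C_d = %.4g\n",
              g$ra_ohm_cm, g$r_coupling_Mohm, x$cd))
  cat(sprintf("  K_Na = %g mM, d_pump_s = %g mA/cm2%s\n",
              x$params$k_na, x$params$d_pump_s,
              if (isTRUE(x$params$alcohol)) ", alcohol ramp ACTIVE" else ""))
  if (x$params$g_bk_s == 0 && x$params$g_bk_d == 0)
    cat("  BK knocked out\n")
  if (x$params$g_erg > 0)
    cat(sprintf("  dendritic ERG inserted at %.4g mS/cm2\n", x$params$g_erg))
  invisible(x)
}
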