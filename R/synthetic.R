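# seeded RNG scoped to a generator call, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a small random branched dendritic tree
#'
#' Seeded, reproducible fixture generator for the reduction algorithm:
#' `n_branches` tapered-cylinder branches with radii and lengths drawn
#' uniformly from the given ranges, attached at random to previously
#' generated branches (branch 1 roots at the soma).  The per-branch radii
#' and lengths are known, so the collapse result is hand-computable.
#'
#' @param n_branches number of branches (>= 1).
#' @param radius_range,length_range uniform sampling ranges (um).
#' @param seed RNG seed.
#' @return A [morph_tree()] (writable with [write_swc()]).
#' @export
gen_synthetic_tree <- function(n_branches, radius_range = c(0.5, 3),
                               length_range = c(20, 200), seed = 1) {
  stopifnot(n_branches >= 1)
  .with_seed(seed, {
    r <- stats::runif(n_branches, radius_range[1], radius_range[2])
    l <- stats::runif(n_branches, length_range[1], length_range[2])
    parent <- c(NA_integer_,
                if (n_branches > 1)
                  vapply(2:n_branches,
                         function(i) sample.int(i - 1L, 1L), integer(1)))
    morph_tree(data.frame(id = seq_len(n_branches), parent_id = parent,
                          radius_um = r, length_um = l))
  })
}

#' Assemble a synthetic voltage trace with known activity states
#'
#' Builds a two-channel (soma + dendrite) voltage trace from a segment
#' plan, emitting the ground-truth labels alongside.  Used to verify the
#' spike detector and the state classifier against a known construction.
#'
#' Plan rows: `label` in `tonic`, `burst`, `quiescent`,
#' `depolarization_block`; `duration_s`; optional `rate_hz` (tonic spike
#' rate, default 40; burst cluster rate, default 2).  Tonic segments place
#' `duration * rate` spikes on a regular grid; burst segments place
#' clusters of 3 spikes at 10 ms intervals, each cluster aligned with a
#' dendritic Ca2+ spike; quiescent segments sit at -65 mV and
#' depolarization-block segments at -40 mV with small (< 5 mV) ripples.
#'
#' @param plan data.frame as above.
#' @param seed RNG seed for the additive noise (0.2 mV s.d.).
#' @param dt_ms sampling step of the synthetic trace (ms).
#' @return A `purkinje_trace`-classed data.frame (`t_ms`, `v_soma`,
#'   `v_dend`) with attributes `labels` (ground-truth segment table) and
#'   `spike_times` (ground-truth somatic spike times, ms).
#' @export
gen_synthetic_trace <- function(plan, seed = 1, dt_ms = 0.5) {
  stopifnot(all(c("label", "duration_s") %in% names(plan)))
  known <- c("tonic", "burst", "quiescent", "depolarization_block")
  if (!all(plan$label %in% known))
    stop("unknown labels: ",
         paste(setdiff(plan$label, known), collapse = ", "))
  total_ms <- sum(plan$duration_s) * 1000
  t <- seq(0, total_ms, by = dt_ms)
  .with_seed(seed, {
    vs <- rep(-65, length(t)) + stats::rnorm(length(t), 0, 0.2)
    vd <- rep(-60, length(t)) + stats::rnorm(length(t), 0, 0.2)
    truth <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                        label = character(0), stringsAsFactors = FALSE)
    spike_times <- numeric(0)

    add_spike <- function(v, at_ms, peak = 20, ahp = -75) {
      i <- findInterval(at_ms, t)
      if (i >= 2 && i < length(t)) {
        v[i] <- peak
        v[i + 1] <- ahp
      }
      v
    }
    add_dend_spike <- function(v, at_ms) {
      # broad Ca2+ spike: ~8 ms above -30 mV
      sel <- t >= at_ms - 4 & t <= at_ms + 4
      v[sel] <- pmax(v[sel], -10 - 2 * abs(t[sel] - at_ms))
      v
    }

    cursor <- 0
    for (k in seq_len(nrow(plan))) {
      dur <- plan$duration_s[k] * 1000
      a <- cursor; b <- cursor + dur
      lab <- plan$label[k]
      sel <- t >= a & t < b
      if (lab == "quiescent") {
        vs[sel] <- -65 + stats::rnorm(sum(sel), 0, 0.2)
      } else if (lab == "depolarization_block") {
        vs[sel] <- -40 + 2 * sin(2 * pi * (t[sel] - a) / 500) +
          stats::rnorm(sum(sel), 0, 0.2)
      } else if (lab == "tonic") {
        rate <- if ("rate_hz" %in% names(plan) && !is.na(plan$rate_hz[k]))
          plan$rate_hz[k] else 40
        n <- round(dur / 1000 * rate)
        at <- a + (seq_len(n) - 0.5) * (dur / n)
        vs[sel] <- -55 + stats::rnorm(sum(sel), 0, 0.2)
        for (s in at) vs <- add_spike(vs, s)
        spike_times <- c(spike_times, at)
      } else if (lab == "burst") {
        rate <- if ("rate_hz" %in% names(plan) && !is.na(plan$rate_hz[k]))
          plan$rate_hz[k] else 2
        n <- max(1, round(dur / 1000 * rate))
        at <- a + (seq_len(n) - 0.5) * (dur / n)
        vs[sel] <- -55 + stats::rnorm(sum(sel), 0, 0.2)
        for (s in at) {
          for (j in 0:2) vs <- add_spike(vs, s + 10 * j)
          vd <- add_dend_spike(vd, s + 10)
          spike_times <- c(spike_times, s + 10 * (0:2))
        }
      }
      truth <- rbind(truth, data.frame(start_ms = a, end_ms = b,
                                       label = lab,
                                       stringsAsFactors = FALSE))
      cursor <- b
    }

    tr <- data.frame(t_ms = t, v_soma = vs, v_dend = vd)
    attr(tr, "dt_ms") <- dt_ms
    attr(tr, "stride") <- 1L
    attr(tr, "labels") <- truth
    attr(tr, "spike_times") <- sort(spike_times)
    class(tr) <- c("purkinje_trace", "data.frame")
    tr
  })
}
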