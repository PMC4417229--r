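#' Detect spikes by threshold crossing
#'
#' One event per upward crossing of `threshold_mv`, with a refractory
#' lockout (default 1 ms) so that a single action potential is never
#' counted twice.  Requires uniform sampling.
#'
#' @param trace a `purkinje_trace` or data.frame with `t_ms` and the
#'   voltage column.
#' @param threshold_mv detection threshold (mV); default -20 for somatic
#'   spikes (-30 is the conventional choice for dendritic Ca2+ spikes).
#' @param compartment `"soma"` or `"dendrite"`.
#' @param lockout_ms minimum separation between events (ms).
#' @return Numeric vector of spike times (ms), strictly increasing;
#'   empty for an empty or sub-threshold trace.
#' @export
detect_spikes <- function(trace, threshold_mv = -20,
                          compartment = c("soma", "dendrite"),
                          lockout_ms = 1) {
  compartment <- match.arg(compartment)
  col <- if (compartment == "soma") "v_soma" else "v_dend"
  if (!col %in% names(trace)) stop("trace has no column '", col, "'")
  v <- trace[[col]]; t <- trace$t_ms
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv) + 1L
  if (!length(up)) return(numeric(0))
  times <- t[up]
  keep <- c(TRUE, diff(times) >= lockout_ms)
  # iterate: removal can re-expose later events to the lockout
  while (any(!keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= lockout_ms)
  }
  times
}

#' Segment a trace into firing states
#'
#' Labels every point of the analysed window as one of `tonic`, `burst`,
#' `quiescent` or `depolarization_block`:
#' * silent stretches (no somatic spike for more than `quiescent_gap_ms`)
#'   are `quiescent` if the mean potential is below `v_split_mv`, else
#'   `depolarization_block` (a depolarized silence, typically furrowed by
#'   small deflections from ongoing dendritic spikes);
#' * spiking stretches are `burst` where spikes cluster (inter-spike
#'   interval below `burst_isi_ms`) and, when a dendritic voltage channel
#'   is available, co-occur with dendritic Ca2+ spikes; the remaining
#'   spiking stretches are `tonic`.
#' Mode runs shorter than `min_mode_ms` are absorbed into their
#' neighbours.  The classification depends only on spike times and mean
#' potentials, so it is invariant to uniform time shifts and to the
#' sampling stride.
#'
#' @param trace a `purkinje_trace` or data.frame with `t_ms`, `v_soma` and
#'   optionally `v_dend`.
#' @param spikes optional precomputed somatic spike times (ms).
#' @param dend_spikes optional precomputed dendritic spike times (ms).
#' @param soma_threshold_mv,dend_threshold_mv detection thresholds (mV).
#' @param quiescent_gap_ms silence duration that opens a non-spiking
#'   segment (ms).
#' @param v_split_mv potential separating quiescence from depolarization
#'   block in silent stretches (mV).
#' @param burst_isi_ms inter-spike interval bound for burst clustering.
#' @param dend_window_ms co-occurrence window linking a somatic spike
#'   cluster to a dendritic spike (ms).
#' @param min_mode_ms minimum mode-run duration (ms).
#' @return data.frame of class `activity_segments` with columns
#'   `start_ms`, `end_ms`, `label`; ordered, non-overlapping, covering
#'   the window.
#' @export
classify_activity <- function(trace, spikes = NULL, dend_spikes = NULL,
                              soma_threshold_mv = -20,
                              dend_threshold_mv = -30,
                              quiescent_gap_ms = 1000, v_split_mv = -50,
                              burst_isi_ms = 30, dend_window_ms = 60,
                              min_mode_ms = 500) {
  t <- trace$t_ms
  if (length(t) < 2) stop("trace is shorter than the classification window")
  t0 <- t[1]; t1 <- t[length(t)]
  if (is.null(spikes))
    spikes <- detect_spikes(trace, soma_threshold_mv, "soma")
  have_dend <- "v_dend" %in% names(trace) || !is.null(dend_spikes)
  if (is.null(dend_spikes) && have_dend)
    dend_spikes <- detect_spikes(trace, dend_threshold_mv, "dendrite")

  silent_label <- function(a, b) {
    # mean V over the gap interior (margins avoid spike tails)
    m <- min(100, (b - a) / 4)
    sel <- t >= a + m & t <= b - m
    if (!any(sel)) sel <- t >= a & t <= b
    if (mean(trace$v_soma[sel]) >= v_split_mv) "depolarization_block"
    else "quiescent"
  }

  if (!length(spikes)) {
    segs <- data.frame(start_ms = t0, end_ms = t1,
                       label = silent_label(t0, t1),
                       stringsAsFactors = FALSE)
    class(segs) <- c("activity_segments", "data.frame")
    return(segs)
  }

  # silent segments: long gaps between spikes and at the window edges
  edges <- c(t0, spikes, t1)
  gaps <- data.frame(a = edges[-length(edges)], b = edges[-1])
  gaps <- gaps[gaps$b - gaps$a > quiescent_gap_ms, , drop = FALSE]

  segs <- if (nrow(gaps))
    data.frame(start_ms = gaps$a, end_ms = gaps$b,
               label = mapply(silent_label, gaps$a, gaps$b),
               stringsAsFactors = FALSE)
  else data.frame(start_ms = numeric(0), end_ms = numeric(0),
                  label = character(0), stringsAsFactors = FALSE)

  # spiking regions are the complement of the silent segments
  bounds <- sort(unique(c(t0, t1, segs$start_ms, segs$end_ms)))
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    if (nrow(segs) && any(segs$start_ms <= a & segs$end_ms >= b)) next
    sp <- spikes[spikes >= a & spikes <= b]
    if (!length(sp)) next
    isi_prev <- c(Inf, diff(sp)); isi_next <- c(diff(sp), Inf)
    bursty <- pmin(isi_prev, isi_next) < burst_isi_ms
    if (have_dend && length(dend_spikes))
      bursty <- bursty & vapply(sp, function(s)
        any(abs(dend_spikes - s) <= dend_window_ms), logical(1))
    else if (have_dend) bursty[] <- FALSE
    flags <- .smooth_flags(sp, bursty, min_mode_ms)
    r <- rle(flags)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
    # boundaries between unlike runs sit midway between the flanking spikes
    cuts <- c(a, (sp[ends_i[-length(ends_i)]] +
                  sp[starts_i[-1]]) / 2, b)
    segs <- rbind(segs, data.frame(
      start_ms = cuts[-length(cuts)], end_ms = cuts[-1],
      label = ifelse(r$values, "burst", "tonic"),
      stringsAsFactors = FALSE))
  }

  segs <- segs[order(segs$start_ms), , drop = FALSE]
  # merge adjacent same-label segments
  keep <- c(TRUE, segs$label[-1] != segs$label[-nrow(segs)] |
                  segs$start_ms[-1] > segs$end_ms[-nrow(segs)] + 1e-9)
  grp <- cumsum(keep)
  segs <- data.frame(
    start_ms = tapply(segs$start_ms, grp, min),
    end_ms = tapply(segs$end_ms, grp, max),
    label = tapply(segs$label, grp, function(l) l[1]),
    stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  class(segs) <- c("activity_segments", "data.frame")
  segs
}

# absorb runs of spike flags shorter than min_mode_ms into their
# neighbourhood (majority vote over a centred window)
.smooth_flags <- function(sp, flags, min_mode_ms) {
  if (length(sp) < 3) return(flags)
  for (pass in 1:2) {
    r <- rle(flags)
    if (length(r$lengths) <= 1) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    dur <- sp[ends] - sp[starts]
    for (k in seq_along(r$lengths)) {
      if (dur[k] >= min_mode_ms || length(r$lengths) == 1) next
      if (k == 1 && length(r$values) > 1)
        flags[starts[k]:ends[k]] <- r$values[2]
      else if (k == length(r$values))
        flags[starts[k]:ends[k]] <- r$values[k - 1]
      else {
        # inner short run: take the longer neighbour's flag
        nb <- if (dur[k - 1] >= dur[k + 1]) r$values[k - 1]
              else r$values[k + 1]
        flags[starts[k]:ends[k]] <- nb
      }
    }
    flags <- as.logical(flags)
  }
  flags
}

#' Per-sample activity labels
#'
#' @param segments an `activity_segments` table.
#' @param t_ms sample times (ms).
#' @return Character vector of labels, one per sample.
#' @export
activity_labels <- function(segments, t_ms) {
  lab <- rep(NA_character_, length(t_ms))
  for (k in seq_len(nrow(segments)))
    lab[t_ms >= segments$start_ms[k] & t_ms <= segments$end_ms[k]] <-
      segments$label[k]
  lab
}

#' Period of the repeating tonic-burst-quiescent motif
#'
#' The period is the mean interval between successive tonic onsets,
#' counting only complete cycles (a tonic onset followed by at least one
#' burst and one quiescent segment before the next tonic onset).
#'
#' @param segments an `activity_segments` table from [classify_activity()].
#' @return Period in seconds, or `NA` (undetermined) if the trace holds no
#'   complete tonic-burst-quiescent cycle.
#' @export
trimodal_period <- function(segments) {
  onsets <- segments$start_ms[segments$label == "tonic"]
  if (length(onsets) < 2) return(NA_real_)
  periods <- numeric(0)
  for (k in seq_len(length(onsets) - 1)) {
    between <- segments$label[segments$start_ms >= onsets[k] &
                              segments$start_ms < onsets[k + 1]]
    if ("burst" %in% between && "quiescent" %in% between)
      periods <- c(periods, onsets[k + 1] - onsets[k])
  }
  if (!length(periods)) return(NA_real_)
  mean(periods) / 1000
}

#' @export
print.activity_segments <- function(x, ...) {
  cat(sprintf("activity segments over [%.3g, %.3g] s:\n",
              min(x$start_ms) / 1000, max(x$end_ms) / 1000))
  for (k in seq_len(nrow(x)))
    cat(sprintf("  %8.2f - %8.2f s  %s\n", x$start_ms[k] / 1000,
                x$end_ms[k] / 1000, x$label[k]))
  invisible(x)
}
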