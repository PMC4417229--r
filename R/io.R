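# configuration files are YAML with three optional blocks:
#   cell:     constructor arguments + named parameter overrides
#   sim:      duration_s, dt_ms, stride, record_ions
#   protocol: name (alcohol | bk_knockout | erg_rescue | kna), args
.config_cell_keys <- c("cd", "dend_length_um", "dend_diam_um",
                       "soma_length_um", "soma_diam_um", "ra_ohm_cm",
                       "overrides")
.config_sim_keys <- c("duration_s", "dt_ms", "stride", "record_ions")

#' Load a simulation configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming the offender),
#' applies the tabulated defaults for every absent mechanism density and
#' refuses negative densities.
#'
#' @param path YAML file path.
#' @return List of class `purkinje_config` with elements `cell`, `sim`,
#'   `protocol`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("cell", "sim", "protocol"))
  if (length(unknown))
    stop("unknown configuration key: ", unknown[1])
  cell <- cfg$cell %||% list()
  unknown <- setdiff(names(cell), .config_cell_keys)
  if (length(unknown)) stop("unknown cell key: ", unknown[1])
  ov <- cell$overrides %||% list()
  defaults <- .default_params()
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stop("unknown parameter override: ", unknown[1])
  gneg <- grepl("^(g_|d_pump|cm_)", names(ov)) & unlist(ov) < 0
  if (any(gneg))
    stop("negative density rejected: ", names(ov)[gneg][1])
  sim <- cfg$sim %||% list()
  unknown <- setdiff(names(sim), .config_sim_keys)
  if (length(unknown)) stop("unknown sim key: ", unknown[1])
  structure(list(cell = cell, sim = sim, protocol = cfg$protocol),
            class = "purkinje_config")
}

#' Save a configuration
#'
#' @param cfg a `purkinje_config` (or plain list with the same blocks).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(list(cell = cfg$cell, sim = cfg$sim,
                        protocol = cfg$protocol), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a cell from a configuration
#'
#' @param cfg a `purkinje_config` from [load_config()].
#' @return A [purkinje_cell()], with any configured protocol applied.
#' @export
build_cell <- function(cfg) {
  cl <- cfg$cell %||% list()
  args <- cl[setdiff(.config_cell_keys, "overrides")]
  args <- args[!vapply(args, is.null, logical(1))]
  cell <- do.call(purkinje_cell, c(args, cl$overrides %||% list()))
  pr <- cfg$protocol
  if (!is.null(pr)) {
    cell <- switch(pr$name,
      alcohol = do.call(alcohol_protocol, c(list(cell), pr$args %||% list())),
      bk_knockout = bk_knockout(cell),
      erg_rescue = add_erg(bk_knockout(cell)),
      kna = set_kna(cell, pr$args$value_mm),
      stop("unknown protocol: ", pr$name))
  }
  cell
}

# full-precision numeric formatting so CSV round-trips are exact
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trace as CSV
#'
#' Comma-separated, '.' decimal, header row; a leading comment line states
#' the units (times in ms, voltages in mV, concentrations in mM) and the
#' sampling metadata.  Values are written at full precision so the file
#' round-trips through [read_trace_csv()] exactly.
#'
#' @param trace a `purkinje_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(
    "# purkinje2c trace; t_ms in ms, v_* in mV, ca_*/na_i/k_o in mM; dt_ms=%.17g stride=%d",
    attr(trace, "dt_ms") %||% NA_real_,
    attr(trace, "stride") %||% 1L), con)
  cols <- names(trace)
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(trace, .fmt_num), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A `purkinje_trace` data.frame with sampling metadata restored.
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1)
  tr <- utils::read.csv(path, comment.char = "#")
  dt <- as.numeric(sub(".*dt_ms=([^ ]+).*", "\\1", header))
  stride <- as.integer(sub(".*stride=([0-9]+).*", "\\1", header))
  attr(tr, "dt_ms") <- dt
  attr(tr, "stride") <- stride
  class(tr) <- c("purkinje_trace", "data.frame")
  tr
}

#' Write an activity-segment table as CSV
#'
#' @param segments an `activity_segments` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# purkinje2c activity segments; start_ms/end_ms in ms", con)
  writeLines("start_ms,end_ms,label", con)
  writeLines(sprintf("%.17g,%.17g,%s", segments$start_ms, segments$end_ms,
                     segments$label), con)
  invisible(path)
}

#' Write or finalize a run manifest
#'
#' A YAML record of a simulation run: configuration hash, package version,
#' integration step, duration, protocol and output files.  Written with
#' `status: started` before the run and finalized afterwards.
#'
#' @param path manifest path.
#' @param cfg the run's `purkinje_config` (hashed into the manifest).
#' @param dt_ms,duration_s integration settings.
#' @param protocol protocol name or `"none"`.
#' @param files character vector of output files.
#' @param status `"started"` or `"finalized"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg, dt_ms, duration_s,
                           protocol = "none", files = character(0),
                           status = c("started", "finalized")) {
  status <- match.arg(status)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  yaml::write_yaml(list(
    package = "purkinje2c",
    version = as.character(utils::packageVersion("purkinje2c")),
    config_md5 = unname(tools::md5sum(tmp)),
    dt_ms = dt_ms, duration_s = duration_s, protocol = protocol,
    outputs = as.list(files), status = status), path)
  invisible(path)
}
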