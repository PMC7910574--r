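#' Write a simulated field as tidy CSV
#'
#' Long format with one row per (time, node): columns `time_s`, `x_mm`,
#' `area_mm2`, `velocity_cm_s`, `pressure_mmhg`. A JSON metadata sidecar
#' (`<path>.meta.json`) records the run configuration and the convergence
#' and conservation metrics.
#'
#' @param field A `hemo_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  nt <- length(field$time_s); nx <- length(field$x_mm)
  df <- data.frame(
    time_s = rep(field$time_s, times = nx),
    x_mm = rep(field$x_mm, each = nt),
    area_mm2 = as.vector(field$area_mm2),
    velocity_cm_s = as.vector(field$velocity_cm_s),
    pressure_mmhg = as.vector(field$pressure_mmhg)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    load = field$load[c("icp", "pio", "pe", "inlet_mean", "inlet_amplitude",
                        "period", "waveform", "outlet_resistance")],
    config = unclass(field$config),
    convergence = field$meta$convergence,
    conservation = field$meta$conservation,
    mean_inlet_flow_ml_s = field$meta$mean_inlet_flow_ml_s
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a probe series as tidy CSV
#'
#' Columns `probe_id`, `time_s`, `area_mm2`, `velocity_cm_s`,
#' `pressure_mmhg`, one row per time moment of the final cycle.
#'
#' @param series A `probe_series`, or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_probe_csv <- function(series, path) {
  if (inherits(series, "probe_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(p) {
    cbind(probe_id = p$location, p$samples)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write two-depth Doppler traces
#'
#' The trace CSV dialect has columns `time_s`, `ps_ioa`, `ps_eoa`,
#' `valid` (0/1). Sampling is assumed uniform; the rate is recovered from
#' the timestamps on read.
#'
#' @param trace A [doppler_trace()].
#' @param path CSV path.
#' @return `write_trace_csv`: `path`, invisibly. `read_trace_csv`: a
#'   [doppler_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  df <- trace$samples
  df$valid <- as.integer(df$valid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "ps_ioa", "ps_eoa", "valid") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  doppler_trace(df$ps_ioa, df$ps_eoa, fs_hz = fs, valid = df$valid > 0)
}

#' Read and write monitoring sessions
#'
#' The session CSV dialect has columns `subject_id`, `time_s`,
#' `icp_inv_mmhg`, `bff`, `valid` (0/1).
#'
#' @param session A [monitoring_session()].
#' @param path CSV path.
#' @return `write_session_csv`: `path`, invisibly. `read_session_csv`: a
#'   [monitoring_session()].
#' @export
write_session_csv <- function(session, path) {
  r <- session$records
  df <- data.frame(subject_id = session$subject, time_s = r$time_s,
                   icp_inv_mmhg = r$icp_inv_mmhg, bff = r$bff,
                   valid = as.integer(r$valid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("subject_id", "time_s", "icp_inv_mmhg", "bff", "valid") %in% names(df)))
  monitoring_session(df$subject_id[1], df$time_s, df$icp_inv_mmhg, df$bff,
                     df$valid > 0)
}

#' Read a model configuration file
#'
#' YAML (or JSON) configuration with optional sections `geometry`, `load`
#' and `sim`; entries override the canonical defaults of [oa_geometry()],
#' [pressure_load()] and [sim_config()]. Unknown keys are rejected.
#'
#' @param path Path to the YAML/JSON configuration file.
#' @return List with elements `geometry`, `load`, `sim`, ready for
#'   [simulate_oa()]. The `load` element is `NULL` when the file sets no
#'   `icp` (callers supply it, e.g. per sweep).
#' @export
read_oa_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, section) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop(sprintf("unknown %s keys: %s", section, paste(extra, collapse = ", ")))
  }
  gsec <- cfg$geometry %||% list()
  check_keys(gsec, names(formals(oa_geometry)), "geometry")
  geometry <- do.call(oa_geometry, lapply(gsec, unlist_named))
  ssec <- cfg$sim %||% list()
  check_keys(ssec, names(formals(sim_config)), "sim")
  sim <- do.call(sim_config, ssec)
  lsec <- cfg$load %||% list()
  check_keys(lsec, names(formals(pressure_load)), "load")
  load <- if (!is.null(lsec$icp)) do.call(pressure_load, lsec) else NULL
  list(geometry = geometry, load = load, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unlist_named <- function(x) if (is.list(x)) unlist(x) else x
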