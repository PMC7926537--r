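#' Read a raw sensor log CSV
#'
#' The log dialect is a plain UTF-8 CSV with header
#' `t,m1x,m1y,m1z,...,m4z,ax,ay,az,gx,gy,gz`: time in seconds,
#' magnetometers as signed integer LSB, accelerometer in g, gyroscope in
#' degrees/s.
#'
#' @param path file path.
#' @return sensor log `data.frame` in time order.
#' @export
read_sensor_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  log <- data.table::fread(path, sep = ",", header = TRUE,
                           data.table = FALSE)
  if (nrow(log) == 0) stop("empty sensor log: ", path)
  missing <- setdiff(sensor_log_columns, names(log))
  if (length(missing) > 0) {
    stop("sensor log is missing columns: ", paste(missing, collapse = ", "))
  }
  log <- log[, sensor_log_columns]
  non_num <- names(log)[!vapply(log, is.numeric, logical(1))]
  bad <- unique(unlist(lapply(log, function(col) which(is.na(col)))))
  if (length(non_num) > 0 || length(bad) > 0) {
    stop(sprintf(
      "unparseable values in sensor log%s%s",
      if (length(non_num)) paste0(" (columns ",
                                  paste(non_num, collapse = ", "), ")")
      else "",
      if (length(bad)) paste0(" at data line(s) ",
                              paste(utils::head(sort(bad), 5), collapse = ", "))
      else ""
    ))
  }
  if (any(diff(log$t) <= 0)) {
    stop(sprintf("time stamps not strictly increasing at data line %d",
                 which(diff(log$t) <= 0)[1] + 1L))
  }
  log
}

#' Write a sensor log CSV
#'
#' @param log sensor log `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  stopifnot(all(sensor_log_columns %in% names(log)))
  data.table::fwrite(log[, sensor_log_columns], path)
  invisible(path)
}

#' Write detected events to CSV
#'
#' Columns `t,trigger,axes,run_x,run_y,run_z`, sorted by time.
#'
#' @param events events `data.frame` from [hand_count()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- events[order(events$t), , drop = FALSE]
  data.table::fwrite(ev, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- data.table::fread(path, data.table = FALSE)
  if (nrow(ev) == 0) return(empty_events())
  ev
}

#' Serialize a calibration to JSON
#'
#' Records sigma, the derived run-length requirements, the parameters the
#' calibration is valid for and a fingerprint of the input data, at full
#' precision, so a calibration round-trips exactly.
#'
#' @param calib a `hand_calibration`.
#' @param path output path.
#' @param input_digest optional fingerprint string of the calibration
#'   input.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path, input_digest = NULL) {
  stopifnot(inherits(calib, "hand_calibration"))
  obj <- list(
    sigma = calib$sigma,
    n_two_axes = calib$n_two_axes,
    n_one_axis = calib$n_one_axis,
    n_runs = calib$n_runs,
    params = calib$params,
    input_digest = input_digest
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- hand_count_params(
    lp_cutoff = obj$params$lp_cutoff,
    threshold = obj$params$threshold,
    sds_two_axes = obj$params$sds_two_axes,
    extra_samples_one_axis = obj$params$extra_samples_one_axis,
    fs = obj$params$fs
  )
  calib <- calibration_from_sigma(obj$sigma, params,
                                  n_runs = obj$n_runs)
  if (calib$n_two_axes != obj$n_two_axes ||
      calib$n_one_axis != obj$n_one_axis) {
    stop("calibration file is internally inconsistent: ", path)
  }
  calib
}

#' Read algorithm parameters from a JSON config
#'
#' Recognised keys: `lp_cutoff_hz` (null for no filtering),
#' `threshold_lsb`, `sds_two_axes`, `extra_samples_one_axis`, `fs_hz`,
#' `reset_timeout_s`.  Missing keys take the device defaults.
#'
#' @param path JSON file path.
#' @return a [hand_count_params()].
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("lp_cutoff_hz", "threshold_lsb", "sds_two_axes",
             "extra_samples_one_axis", "fs_hz", "reset_timeout_s")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  pick <- function(key, default) {
    if (is.null(obj[[key]])) default else obj[[key]]
  }
  hand_count_params(
    lp_cutoff = if ("lp_cutoff_hz" %in% names(obj)) obj$lp_cutoff_hz else 8,
    threshold = pick("threshold_lsb", 8),
    sds_two_axes = pick("sds_two_axes", 5),
    extra_samples_one_axis = pick("extra_samples_one_axis", 2),
    fs = pick("fs_hz", default_fs),
    reset_timeout = pick("reset_timeout_s", 2)
  )
}

#' Write / read a counting-probability table
#'
#' @param tab `data.frame` from [counting_probability()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_probability_table <- function(tab, path) {
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

# Cheap deterministic fingerprint of a numeric data.frame, recorded with
# calibrations for provenance.
log_fingerprint <- function(d) {
  num <- vapply(d, is.numeric, logical(1))
  sprintf("n=%d;sum=%.10g", nrow(d),
          sum(vapply(d[num], sum, numeric(1))))
}
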