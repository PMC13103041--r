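# Continuous multi-channel recording container.

#' Channel roles for the standard mobile-EEG montage
#'
#' Maps channel names to roles: occipital/parietal EEG (`O1 O2 P3 P4 P7 P8`),
#' vertical/horizontal EOG (`EOGv`, `EOGh`) and the amplifier's 3-axis
#' accelerometer (`ACCx`, `ACCy`, `ACCz`).
#'
#' @param names Character vector of channel names.
#' @return Named character vector of roles, one of `EEG`, `EOG_v`, `EOG_h`,
#'   `ACC_x`, `ACC_y`, `ACC_z`.
#' @export
default_channel_roles <- function(names) {
  map <- c(
    O1 = "EEG", O2 = "EEG", P3 = "EEG", P4 = "EEG", P7 = "EEG", P8 = "EEG",
    EOGv = "EOG_v", EOGh = "EOG_h",
    ACCx = "ACC_x", ACCy = "ACC_y", ACCz = "ACC_z"
  )
  unknown <- setdiff(names, names(map))
  if (length(unknown) > 0) {
    stop("unknown channel role for: ", paste(unknown, collapse = ", "),
         "; supply `roles` explicitly", call. = FALSE)
  }
  stats::setNames(map[names], names)
}

#' Construct a continuous recording
#'
#' @param data Numeric matrix, samples x channels, with channel names as
#'   column names. EEG/EOG channels are in microvolts, accelerometer channels
#'   in milli-g.
#' @param fs Sampling rate in Hz.
#' @param triggers Integer sample indices (1-based) of flicker darkening
#'   onsets; strictly increasing, within the recording. May be empty.
#' @param roles Named character vector of channel roles; defaults to
#'   [default_channel_roles()] applied to the column names.
#' @param meta Named list of trial metadata (`participant`, `session`,
#'   `scene`, `trial`, `flicker_freq`, ...).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, triggers = integer(), roles = NULL,
                      meta = list()) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) {
    stop("`data` must have channel names as column names", call. = FALSE)
  }
  stopifnot_scalar_numeric(fs, "fs", positive = TRUE)
  triggers <- as.integer(triggers)
  if (length(triggers) > 0) {
    if (any(diff(triggers) <= 0)) {
      stop("`triggers` must be strictly increasing", call. = FALSE)
    }
    if (min(triggers) < 1 || max(triggers) > nrow(data)) {
      stop("`triggers` out of the recorded time range", call. = FALSE)
    }
  }
  roles <- roles %||% default_channel_roles(colnames(data))
  missing_role <- setdiff(colnames(data), names(roles))
  if (length(missing_role) > 0) {
    stop("no role for channel(s): ", paste(missing_role, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      data = data, fs = fs, triggers = triggers,
      roles = roles[colnames(data)], meta = meta,
      filter_tag = meta$filter_tag %||% "none",
      edge_exclude = 0
    ),
    class = "eeg_recording"
  )
}

#' Channel names with a given role
#'
#' @param rec An `eeg_recording`.
#' @param role One or more roles, e.g. `"EEG"` or `c("EOG_v", "EOG_h")`.
#' @return Character vector of matching channel names.
#' @export
channels_with_role <- function(rec, role) {
  names(rec$roles)[rec$roles %in% role]
}

n_samples <- function(rec) nrow(rec$data)

rec_duration <- function(rec) nrow(rec$data) / rec$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d triggers\n",
    ncol(x$data), nrow(x$data), x$fs, rec_duration(x), length(x$triggers)
  ))
  if (length(x$meta) > 0) {
    kv <- vapply(x$meta, function(v) paste(format(v), collapse = ","), "")
    cat("  meta:", paste(names(kv), kv, sep = "=", collapse = " "), "\n")
  }
  if (!identical(x$filter_tag, "none")) cat("  filter:", x$filter_tag, "\n")
  invisible(x)
}
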