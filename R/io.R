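# Reading and writing continuous recordings: BrainVision triplets
# (.vhdr/.vmrk/.eeg) and a delimited-text fallback with a TRIG column.

#' Write a recording as delimited text
#'
#' Tab-separated file with a header row of channel names plus a `TRIG`
#' column that is 1 at each flicker darkening onset and 0 elsewhere.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_delimited_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  trig <- integer(n_samples(rec))
  trig[rec$triggers] <- 1L
  dt <- data.table::as.data.table(rec$data)
  data.table::set(dt, j = "TRIG", value = trig)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a delimited-text recording
#'
#' @param path File written by [write_delimited_recording()] (or any
#'   delimited file with one column per channel and a 0/1 `TRIG` column).
#' @param fs Sampling rate in Hz (not stored in the text format).
#' @param roles Channel roles; defaults to [default_channel_roles()].
#' @param meta Metadata list attached to the recording.
#' @return An [recording()].
#' @export
read_delimited_recording <- function(path, fs = 1000, roles = NULL, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t")
  if (!"TRIG" %in% names(dt)) {
    stop("delimited recording must contain a TRIG column", call. = FALSE)
  }
  trig_col <- dt[["TRIG"]]
  data.table::set(dt, j = "TRIG", value = NULL)
  recording(as.matrix(dt), fs, triggers = which(trig_col != 0),
            roles = roles, meta = meta)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (multiplexed binary)
#' with one `Stimulus,S  1` marker per flicker trigger.
#'
#' @param rec An [recording()].
#' @param base Path prefix without extension.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`; INT_16 is
#'   stored with the per-channel `resolution` (default 0.1 microvolt/count).
#' @param resolution Scaling for INT_16 storage.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, base, binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  binary_format <- match.arg(binary_format)
  base_name <- basename(base)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  res <- if (binary_format == "INT_16") resolution else 1
  units <- ifelse(startsWith(rec$roles, "ACC"), "mg", "µV")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; written by ssvepshape",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base_name, ".eeg"),
    paste0("MarkerFile=", base_name, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ncol(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,%s", seq_len(ncol(rec$data)), colnames(rec$data),
            format(res, scientific = FALSE), units)
  )
  writeLines(hdr, vhdr, useBytes = FALSE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base_name, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (length(rec$triggers) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S  1,%d,1,0",
                        seq_along(rec$triggers) + 1L, rec$triggers))
  }
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  flat <- as.vector(t(rec$data)) # multiplexed: all channels of sample 1, ...
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(flat, con, size = 4, endian = "little")
  } else {
    counts <- as.integer(round(flat / resolution))
    if (any(abs(counts) > 32767)) {
      stop("INT_16 overflow; increase `resolution`", call. = FALSE)
    }
    writeBin(counts, con, size = 2, endian = "little")
  }
  invisible(vhdr)
}

parse_vhdr_ini <- function(lines) {
  section <- ""
  kv <- list()
  channels <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      if (section == "Channel Infos" && grepl("^Ch[0-9]+$", key)) {
        channels[[key]] <- strsplit(val, ",")[[1]]
      } else {
        kv[[paste(section, key, sep = "/")]] <- val
      }
    }
  }
  list(kv = kv, channels = channels)
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE_FLOAT_32 or INT_16 format;
#' `Stimulus` markers become trigger indices.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @param roles Channel roles; defaults to [default_channel_roles()].
#' @param meta Metadata list attached to the recording.
#' @return An [recording()].
#' @export
read_brainvision <- function(vhdr, roles = NULL, meta = list()) {
  if (!file.exists(vhdr)) stop("header file not found: ", vhdr, call. = FALSE)
  parsed <- parse_vhdr_ini(readLines(vhdr, warn = FALSE))
  kv <- parsed$kv
  dirn <- dirname(vhdr)
  data_file <- file.path(dirn, kv[["Common Infos/DataFile"]])
  marker_file <- file.path(dirn, kv[["Common Infos/MarkerFile"]])
  if (!file.exists(marker_file)) {
    stop("marker file not found: ", marker_file, call. = FALSE)
  }
  if (!identical(kv[["Common Infos/DataOrientation"]], "MULTIPLEXED")) {
    stop("only MULTIPLEXED data orientation is supported", call. = FALSE)
  }
  n_chan <- as.integer(kv[["Common Infos/NumberOfChannels"]])
  fs <- 1e6 / as.numeric(kv[["Common Infos/SamplingInterval"]])
  fmt <- kv[["Binary Infos/BinaryFormat"]]
  ch_info <- parsed$channels[paste0("Ch", seq_len(n_chan))]
  ch_names <- vapply(ch_info, `[`, "", 1)
  ch_res <- vapply(ch_info, function(x) {
    r <- suppressWarnings(as.numeric(x[3]))
    if (is.na(r)) 1 else r
  }, 1)

  sz <- file.info(data_file)$size
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    flat <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    flat <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
    flat <- flat * rep(ch_res, length.out = length(flat))
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  data <- matrix(flat, ncol = n_chan, byrow = TRUE,
                 dimnames = list(NULL, ch_names))

  mk_lines <- readLines(marker_file, warn = FALSE)
  stim <- grep("^Mk[0-9]+=Stimulus,", mk_lines, value = TRUE)
  triggers <- if (length(stim) > 0) {
    sort(vapply(strsplit(sub("^Mk[0-9]+=", "", stim), ","),
                function(x) as.integer(x[3]), 1L))
  } else {
    integer()
  }
  recording(data, fs, triggers = triggers, roles = roles, meta = meta)
}

#' Read a recording in either supported dialect
#'
#' @param path `.vhdr` path for BrainVision, or a delimited-text file.
#' @param dialect `"auto"` (by extension), `"brainvision"` or `"delimited"`.
#' @param ... Passed on to [read_brainvision()] / [read_delimited_recording()].
#' @return An [recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "brainvision", "delimited"),
                           ...) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vhdr$", path)) "brainvision" else "delimited"
  }
  switch(dialect,
    brainvision = read_brainvision(path, ...),
    delimited = read_delimited_recording(path, ...)
  )
}

#' Write all recordings of a study plus its metadata table
#'
#' @param study An [make_study()] result.
#' @param dir Output directory (created if needed).
#' @param dialect `"delimited"` (default) or `"brainvision"`.
#' @return The directory, invisibly; recordings are named
#'   `rec_<idx>_<participant>_<kind>.<ext>` and metadata is `metadata.csv`.
#' @export
write_study <- function(study, dir, dialect = c("delimited", "brainvision")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- study$metadata
  files <- character(nrow(md))
  for (i in seq_len(nrow(md))) {
    rec <- study$recordings[[md$idx[i]]]
    stem <- sprintf("rec_%03d_%s_%s", md$idx[i], md$participant[i], md$kind[i])
    if (dialect == "delimited") {
      files[i] <- paste0(stem, ".tsv")
      write_delimited_recording(rec, file.path(dir, files[i]))
    } else {
      files[i] <- paste0(stem, ".vhdr")
      write_brainvision(rec, file.path(dir, stem))
    }
  }
  md$file <- files
  data.table::fwrite(md, file.path(dir, "metadata.csv"))
  invisible(dir)
}
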