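#' Construct a multichannel recording
#'
#' The basic container for raw or preprocessed biosignal data: a
#' samples-by-channels numeric matrix, the sampling rate, a role for each
#' channel (EEG, ECG, EOG or AUX) and timestamped event markers.
#'
#' @param data numeric matrix, samples in rows, channels in columns.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per column of `data`.
#' @param channel_roles character vector of roles, one of `"EEG"`,
#'   `"ECG"`, `"EOG"`, `"AUX"`. Defaults to `"EEG"` everywhere.
#' @param events data.frame with columns `time` (seconds) and `label`,
#'   or `NULL`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_names = colnames(data),
                      channel_roles = NULL, events = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(ncol(data)))
  }
  if (is.null(channel_roles)) channel_roles <- rep("EEG", ncol(data))
  channel_roles <- match.arg(channel_roles, c("EEG", "ECG", "EOG", "AUX"),
                             several.ok = TRUE)
  if (length(channel_roles) == 1L) {
    channel_roles <- rep(channel_roles, ncol(data))
  }
  stopifnot(
    fs > 0,
    length(channel_names) == ncol(data),
    length(channel_roles) == ncol(data)
  )
  colnames(data) <- channel_names
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), label = character(0),
                         stringsAsFactors = FALSE)
  }
  dur <- nrow(data) / fs
  if (nrow(events) && (any(events$time < 0) || any(events$time > dur))) {
    stop("event times must lie within [0, duration]")
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         channel_roles = channel_roles, events = events),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs
  ))
  tab <- table(x$channel_roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if (nrow(x$events)) cat("  events:", nrow(x$events), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$fs

channels_by_role <- function(rec, role) {
  rec$channel_names[rec$channel_roles %in% role]
}

#' Write a recording as CSV plus a JSON sidecar
#'
#' The signal matrix goes to `<path>` as a headered CSV (one column per
#' channel, one row per sample); sampling rate, channel roles, events and
#' any attached ground truth go to `<path>.json`.
#'
#' @param rec a `recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  utils::write.csv(as.data.frame(rec$data), path, row.names = FALSE)
  meta <- list(
    fs = rec$fs,
    channel_names = rec$channel_names,
    channel_roles = rec$channel_roles,
    events = rec$events
  )
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from CSV (+ JSON sidecar)
#'
#' Inverse of [write_recording()]. If no sidecar is present, `fs` must be
#' supplied and channel roles are inferred from the column names (a column
#' named like "ECG" gets role ECG, like "EOG"/"VEOG"/"HEOG" gets EOG, the
#' rest EEG).
#'
#' @param path CSV path written by [write_recording()], or any headered
#'   CSV of samples-by-channels signal data.
#' @param fs sampling rate in Hz; overrides the sidecar when given.
#' @return A `recording`.
#' @export
read_recording <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e))
  )
  if (!nrow(dat) || !ncol(dat)) stop("malformed CSV '", path, "': empty")
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    stop("malformed CSV '", path, "': non-numeric signal columns")
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  roles <- NULL
  events <- NULL
  if (!is.null(meta)) {
    fs <- fs %||% meta$fs
    roles <- meta$channel_roles
    if (length(meta$events)) events <- as.data.frame(meta$events)
  }
  if (is.null(fs)) stop("no sidecar for '", path, "': supply fs")
  if (is.null(roles)) {
    nm <- toupper(colnames(dat))
    roles <- ifelse(grepl("ECG", nm), "ECG",
                    ifelse(grepl("EOG", nm), "EOG", "EEG"))
  }
  recording(as.matrix(dat), fs = fs, channel_names = colnames(dat),
            channel_roles = roles, events = events)
}
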