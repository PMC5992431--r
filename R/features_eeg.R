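#' Band power of a signal segment
#'
#' Integrated periodogram power over `lo <= f < hi`: the FFT is taken on
#' the demeaned (optionally Hann-tapered) segment and the one-sided
#' periodogram bins falling in the band are summed. With the rectangular
#' taper the sum over a partition of (0, Nyquist\] equals the segment
#' variance exactly (Parseval); the Hann taper uses a power
#' normalization, so broadband power is preserved and a pure tone whose
#' spectral smear lies inside the band integrates to its full power
#' A^2/2.
#'
#' @param segment numeric vector (one channel), at least 1 s of samples.
#' @param fs sampling rate in Hz.
#' @param band numeric `c(lo, hi)` in Hz, within Nyquist.
#' @param taper `"hann"` (default) or `"rectangular"`.
#' @return Non-negative scalar power (signal units squared).
#' @export
band_power <- function(segment, fs, band, taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  stopifnot(length(band) == 2, band[1] < band[2], band[1] >= 0)
  if (band[2] > fs / 2 + 1e-9) stop("band extends above Nyquist")
  if (length(segment) < fs) stop("segment must be at least 1 s long")
  ps <- periodogram_bins(matrix(segment, ncol = 1), fs, taper)
  sum(ps$power[band_bin_select(ps$freq, band[1], band[2], fs), 1])
}

# One-sided periodogram of each column; power normalized so that the sum
# over all bins equals the (taper-corrected) variance.
periodogram_bins <- function(segmat, fs, taper = "hann") {
  n <- nrow(segmat)
  segmat <- sweep(segmat, 2, colMeans(segmat))
  if (taper == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
    segmat <- segmat * w
    corr <- mean(w^2)
  } else {
    corr <- 1
  }
  X <- stats::mvfft(segmat)
  half <- floor(n / 2)
  k <- seq_len(half) # bins 1..n/2 (positive frequencies incl. Nyquist)
  P <- (abs(X[k + 1, , drop = FALSE])^2) / (n^2 * corr)
  two_sided <- rep(2, half)
  if (n %% 2 == 0) two_sided[half] <- 1 # Nyquist bin is unique
  P <- P * two_sided
  list(freq = k * fs / n, power = P)
}

# Half-open band membership lo <= f < hi; a band ending at Nyquist
# includes the Nyquist bin so that a band partition of (0, Nyquist]
# satisfies Parseval exactly.
band_bin_select <- function(freq, lo, hi, fs) {
  sel <- freq >= lo & freq < hi
  if (abs(hi - fs / 2) < 1e-9) sel <- sel | abs(freq - hi) < 1e-9
  sel
}

# Band powers for every channel of a segment matrix (samples x channels):
# returns channels x bands matrix.
band_power_matrix <- function(segmat, fs, bands = eeg_band_table(),
                              taper = "hann") {
  ps <- periodogram_bins(segmat, fs, taper)
  out <- matrix(0, ncol(segmat), nrow(bands),
                dimnames = list(colnames(segmat), bands$band))
  for (bi in seq_len(nrow(bands))) {
    sel <- band_bin_select(ps$freq, bands$lo[bi], bands$hi[bi], fs)
    out[, bi] <- colSums(ps$power[sel, , drop = FALSE])
  }
  out
}

# Compute a feature table (one row per window x channel, one column per
# band) for a set of windows on the EEG channels of a recording.
window_feature_table <- function(rec, windows, bands = eeg_band_table(),
                                 channels = NULL, taper = "hann",
                                 relative = FALSE) {
  channels <- channels %||% retained_eeg(rec)
  validate_band_table(bands)
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    i0 <- floor(windows$start[i] * rec$fs) + 1L
    i1 <- floor(windows$end[i] * rec$fs)
    seg <- rec$data[i0:i1, channels, drop = FALSE]
    pw <- band_power_matrix(seg, rec$fs, bands, taper)
    if (relative) pw <- pw / pmax(rowSums(pw), 1e-300)
    df <- as.data.frame(pw)
    df$channel <- channels
    df$window_id <- i
    df$start <- windows$start[i]
    df$end <- windows$end[i]
    df$label <- if ("label" %in% names(windows)) windows$label[i] else "unlabeled"
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  out$task <- attr(rec, "task") %||% windows$task[1] %||% NA_character_
  rownames(out) <- NULL
  out[, c("window_id", "start", "end", "channel", bands$band, "label",
          "task")]
}

#' Labeled training windows for the fatigue and stress models
#'
#' Cuts a calibration-task recording into contiguous non-overlapping 10 s
#' windows (trailing partial window dropped) and labels them for the
#' requested biometric: for fatigue, breath-count windows are labeled
#' `low` and only the second half of the 3-back task is used, labeled
#' `high` (the first half is discarded so the high-fatigue class reflects
#' accumulated time on task); for stress, breath-count is `low` and the
#' whole 3-back task is `high` (stress rises with load on a fast time
#' scale, so the entire task represents the high state).
#'
#' @param rec a cleaned `recording` of one calibration task (>= 20 s).
#' @param biometric `"fatigue"` or `"stress"`.
#' @param task `"breath_count"` or `"nback3"`; defaults to the
#'   recording's `task` attribute.
#' @param window window length in seconds (10 s).
#' @param ... passed to the feature extractor (`bands`, `channels`,
#'   `taper`, `relative`).
#' @return A feature data.frame, one row per window x channel, with band
#'   columns and a `label` column in `{low, high}`.
#' @export
training_windows <- function(rec, biometric = c("fatigue", "stress"),
                             task = NULL, window = 10, ...) {
  biometric <- match.arg(biometric)
  task <- task %||% attr(rec, "task")
  task <- match.arg(task, c("breath_count", "nback3"))
  dur <- recording_duration(rec)
  if (dur < 2 * window) stop("task segment too short: need at least ",
                             2 * window, " s")
  seg_start <- 0
  label <- "low"
  if (task == "nback3") {
    label <- "high"
    if (biometric == "fatigue") seg_start <- dur / 2
  }
  starts <- seq(seg_start, dur - window, by = window)
  starts <- starts[starts + window <= dur + 1e-9]
  if (!length(starts)) stop("empty task segment after windowing")
  windows <- data.frame(start = starts, end = starts + window,
                        label = label)
  out <- window_feature_table(rec, windows, ...)
  out$task <- task
  out
}

#' Event-locked attention windows from mind-wandering button presses
#'
#' For each button press at time `e`, EEG from `[e - 8, e - 2]` is
#' labeled inattentive (the self-caught mind-wandering bout precedes the
#' press) and `[e + 2, e + 8]` attentive. Any attentive window that
#' overlaps an inattentive window of another event is relabeled
#' inattentive, since the press evidently did not start a sustained
#' attentive period. Events whose windows would extend past the recording
#' edges are dropped. Subjects with fewer than 3 usable events are
#' excluded: an empty table with attribute `excluded = TRUE` is returned.
#'
#' @param rec a cleaned breath-count `recording`.
#' @param mw_events button-press times in seconds.
#' @param ... passed to the feature extractor.
#' @return Feature data.frame with 6 s windows labeled
#'   `inattentive`/`attentive` (or an empty, `excluded`-flagged table).
#' @export
attention_windows <- function(rec, mw_events, ...) {
  dur <- recording_duration(rec)
  ev <- mw_events[mw_events - 8 >= 0 & mw_events + 8 <= dur]
  if (length(ev) < 3) {
    message("subject excluded for attention: fewer than 3 mind-wandering events")
    out <- data.frame()
    attr(out, "excluded") <- TRUE
    return(out)
  }
  inatt <- data.frame(start = ev - 8, end = ev - 2, label = "inattentive",
                      event = ev)
  att <- data.frame(start = ev + 2, end = ev + 8, label = "attentive",
                    event = ev)
  for (i in seq_len(nrow(att))) {
    other <- inatt[inatt$event != att$event[i], , drop = FALSE]
    if (nrow(other) && any(intervals_overlap(att$start[i], att$end[i],
                                             other$start, other$end))) {
      att$label[i] <- "inattentive"
    }
  }
  windows <- rbind(inatt, att)
  windows <- windows[order(windows$start), ]
  out <- window_feature_table(rec, windows[, c("start", "end", "label")],
                              ...)
  attr(out, "excluded") <- FALSE
  out
}

#' Sliding unlabeled test windows
#'
#' Overlapping windows at a 1 s stride: 10 s windows for fatigue and
#' stress, 6 s for attention. The window timestamp is its center.
#'
#' @param rec a `recording` at least one window long.
#' @param biometric `"fatigue"`, `"stress"` or `"attention"`.
#' @param stride stride in seconds.
#' @param ... passed to the feature extractor.
#' @return Feature data.frame with a `center` timestamp column.
#' @export
test_windows <- function(rec, biometric = c("fatigue", "stress", "attention"),
                         stride = 1, ...) {
  biometric <- match.arg(biometric)
  window <- if (biometric == "attention") 6 else 10
  dur <- recording_duration(rec)
  if (dur < window) stop("recording shorter than the test window (",
                         window, " s)")
  starts <- seq(0, dur - window, by = stride)
  windows <- data.frame(start = starts, end = starts + window)
  out <- window_feature_table(rec, windows, ...)
  out$center <- (out$start + out$end) / 2
  out
}
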