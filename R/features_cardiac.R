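#' Detect R peaks in an ECG signal
#'
#' A Pan-Tompkins-style detector: 5-30 Hz band-pass, squared derivative,
#' 150 ms moving-window integration, then peak picking above an adaptive
#' threshold with a 300 ms refractory period; each detection is refined
#' to the band-passed signal maximum within +/- 75 ms. Intervals below
#' the physiological floor (0.3 s) are merged (the weaker detection is
#' dropped) and gaps above 2 s are flagged.
#'
#' @param ecg numeric vector (one ECG channel) of at least 10 s, or a
#'   `recording` whose ECG channel is used.
#' @param fs sampling rate in Hz, >= 250.
#' @return A `beat_series`: list with `peak_times` (s, strictly
#'   increasing), `rr` (successive differences, s) and `long_gaps`.
#' @export
detect_r_peaks <- function(ecg, fs = NULL) {
  if (inherits(ecg, "recording")) {
    ch <- channels_by_role(ecg, "ECG")
    if (!length(ch)) stop("recording has no ECG channel")
    fs <- ecg$fs
    ecg <- ecg$data[, ch[1]]
  }
  stopifnot(!is.null(fs), fs >= 250)
  if (length(ecg) < 10 * fs) stop("ECG must be at least 10 s long")
  bp <- signal::butter(3, c(5, 30) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg)
  d <- c(0, diff(xf)) * fs
  integ <- centered_moving_average(d^2, round(0.15 * fs))
  thr <- 0.3 * stats::quantile(integ, 0.98)
  if (thr <= 0 || !is.finite(thr) || stats::sd(ecg) == 0) {
    stop_mentalstate("unusable ECG signal: no QRS energy detected",
                     "unusable_signal")
  }
  above <- integ > thr
  # candidate peaks: local maxima of the integrated signal above threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(integ[seg])])
  }
  if (length(cand) < 5) {
    stop_mentalstate("unusable ECG signal: fewer than 5 beats detected",
                     "unusable_signal")
  }
  # refine to the band-passed maximum within +/- 75 ms
  half <- round(0.075 * fs)
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(xf), i + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # merge sub-physiological intervals, keeping the stronger peak
  min_rr <- round(0.3 * fs)
  repeat {
    gaps <- diff(peaks)
    j <- which(gaps < min_rr)
    if (!length(gaps) || !length(j)) break
    j <- j[1]
    drop <- if (xf[peaks[j]] >= xf[peaks[j + 1]]) j + 1 else j
    peaks <- peaks[-drop]
  }
  if (length(peaks) < 5) {
    stop_mentalstate("unusable ECG signal: fewer than 5 beats detected",
                     "unusable_signal")
  }
  pt <- (peaks - 1) / fs
  rr <- diff(pt)
  structure(
    list(peak_times = pt, rr = rr, long_gaps = pt[which(rr > 2)]),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, mean RR %.3f s (%.1f bpm)\n",
              length(x$peak_times), mean(x$rr), 60 / mean(x$rr)))
  invisible(x)
}

#' Heart-rate-variability spectrum of a beat series
#'
#' The RR tachogram (each interval timestamped at its closing beat) is
#' linearly interpolated to a uniform 4 Hz grid over the requested
#' window, linearly detrended, and its rectangular-taper periodogram
#' returned. Total power over all returned bins equals the variance of
#' the interpolated, detrended series (Parseval). The physiologically
#' interpreted range is 0.01-0.5 Hz; bins up to the 2 Hz interpolation
#' Nyquist are returned so the Parseval identity is exact.
#'
#' @param beats a `beat_series`.
#' @param window `c(start, end)` in seconds; must contain >= 8 beats.
#' @param fs_interp interpolation rate in Hz (default 4).
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
hrv_spectrum <- function(beats, window = range(beats$peak_times),
                         fs_interp = 4) {
  inside <- beats$peak_times >= window[1] & beats$peak_times <= window[2]
  if (sum(inside) < 8) {
    stop_mentalstate("too few beats in window (need >= 8)", "too_few_beats")
  }
  pt <- beats$peak_times[inside]
  rr_t <- pt[-1]
  rr <- diff(pt)
  grid <- seq(rr_t[1], rr_t[length(rr_t)], by = 1 / fs_interp)
  x <- stats::approx(rr_t, rr, xout = grid)$y
  x <- stats::lm.fit(cbind(1, grid), x)$residuals
  ps <- periodogram_bins(matrix(x, ncol = 1), fs_interp,
                         taper = "rectangular")
  data.frame(freq = ps$freq, power = ps$power[, 1])
}

#' HRV band features
#'
#' Integrates an HRV spectrum into stress features: mode `Ps2_bands`
#' gives the three canonical bands (VLF 0.01-0.04, LF 0.04-0.15, HF
#' 0.15-0.4 Hz); mode `Ps1_bins` gives four 0.1 Hz-wide bins covering
#' 0.01-0.4 Hz.
#'
#' @param spectrum data.frame from [hrv_spectrum()].
#' @param mode `"Ps2_bands"` or `"Ps1_bins"`.
#' @return Named non-negative numeric vector (3 or 4 features).
#' @export
hrv_band_features <- function(spectrum, mode = c("Ps2_bands", "Ps1_bins")) {
  mode <- match.arg(mode)
  edges <- if (mode == "Ps2_bands") {
    with(hrv_band_table(), data.frame(name = band, lo = lo, hi = hi))
  } else {
    data.frame(name = paste0("bin", 1:4),
               lo = c(0.01, 0.1, 0.2, 0.3), hi = c(0.1, 0.2, 0.3, 0.4))
  }
  out <- vapply(seq_len(nrow(edges)), function(i) {
    sel <- spectrum$freq >= edges$lo[i] & spectrum$freq < edges$hi[i]
    if (i == nrow(edges)) { # close the last band at its upper edge
      sel <- sel | abs(spectrum$freq - edges$hi[i]) < 1e-12
    }
    sum(spectrum$power[sel])
  }, numeric(1))
  names(out) <- edges$name
  out
}

#' Per-window cardiac features from a longer HRV context
#'
#' Each (10 s or 6 s) feature bin gets HRV features computed from a
#' longer context window centered on the bin (default 120 s, clipped at
#' the recording edges): the very-low-frequency band at 0.01 Hz is not
#' resolvable inside a 10 s bin, so a shared sliding context supplies the
#' spectral estimate while the bin timeline is preserved. Bins whose
#' context holds fewer than 8 beats get `NA` features and are flagged.
#'
#' @param beats a `beat_series`.
#' @param windows data.frame with `start`, `end` columns (seconds),
#'   sorted.
#' @param mode `"Ps2_bands"` or `"Ps1_bins"`.
#' @param context context length in seconds (default 120).
#' @param span recording time span `c(t0, t1)` used for clipping.
#' @return data.frame: `window_id`, `start`, `end`, feature columns, and
#'   a logical `missing` flag.
#' @export
cardiac_window_features <- function(beats, windows,
                                    mode = c("Ps2_bands", "Ps1_bins"),
                                    context = 120,
                                    span = range(beats$peak_times)) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(windows$start))
  nfeat <- if (mode == "Ps2_bands") 3L else 4L
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    mid <- (windows$start[i] + windows$end[i]) / 2
    w0 <- max(mid - context / 2, span[1])
    w1 <- min(mid + context / 2, span[2])
    feat <- tryCatch(
      hrv_band_features(hrv_spectrum(beats, c(w0, w1)), mode),
      mentalstate_error = function(e) rep(NA_real_, nfeat)
    )
    rows[[i]] <- data.frame(window_id = i, start = windows$start[i],
                            end = windows$end[i], t(feat))
  }
  out <- do.call(rbind, rows)
  nm <- if (mode == "Ps2_bands") hrv_band_table()$band else paste0("bin", 1:4)
  names(out)[4:(3 + nfeat)] <- nm
  out$missing <- !stats::complete.cases(out[, nm, drop = FALSE])
  if ("label" %in% names(windows)) out$label <- windows$label
  out
}
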