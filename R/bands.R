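#' EEG spectral band table
#'
#' The six canonical EEG bands used throughout the package: delta 1-3 Hz,
#' theta 4-8 Hz, alpha 8-12 Hz, beta 13-30 Hz, gamma 30-50 Hz and
#' high-gamma 50-100 Hz. Band membership of a DFT bin is half-open,
#' `lo <= f < hi`.
#'
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_band_table <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"),
    lo = c(1, 4, 8, 13, 30, 50),
    hi = c(3, 8, 12, 30, 50, 100),
    stringsAsFactors = FALSE
  )
}

#' HRV spectral band table
#'
#' Frequency bands of the heart-rate-variability (RR tachogram) spectrum:
#' VLF 0.01-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz. Low-frequency power
#' indexes sympathetic influence and high-frequency power parasympathetic
#' influence on heart rhythm.
#'
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
hrv_band_table <- function() {
  data.frame(
    band = c("VLF", "LF", "HF"),
    lo = c(0.01, 0.04, 0.15),
    hi = c(0.04, 0.15, 0.40),
    stringsAsFactors = FALSE
  )
}

validate_band_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("band", "lo", "hi") %in% names(tab)))
  if (any(tab$lo <= 0) || any(tab$hi <= tab$lo)) {
    stop("band table must satisfy 0 < lo < hi for every band")
  }
  invisible(tab)
}
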