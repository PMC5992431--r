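#' Synthesize an ECG recording with stress-modulated heart-rate variability
#'
#' RR intervals follow
#' `RRmean + a_LF sin(2 pi 0.1 t + phi) + a_HF sin(2 pi 0.3 t + psi) + jitter`,
#' where the LF modulation amplitude increases with the stress latent
#' (`a_LF = lf_amp * (1 + lf_gain * stress)`) and the HF amplitude
#' decreases (`a_HF = hf_amp * (1 - hf_gain * stress)`), so the LF/HF
#' spectral balance of the tachogram rises under stress. The waveform is a
#' QRS-like template (plus a small T wave) placed at each beat time; true
#' beat times are exported as ground truth.
#'
#' @param latents a [generate_latents()] trajectory.
#' @param profile a [subject_profile()].
#' @param fs sampling rate in Hz, >= 250.
#' @return A single-channel `recording` with role ECG and ground-truth
#'   beat times in `attr(, "ground_truth")$beat_times`.
#' @export
synthesize_ecg <- function(latents, profile = subject_profile(), fs = 500) {
  stopifnot(fs >= 250)
  duration <- max(latents$times)
  beats <- with_seed(child_seed(profile$seed, paste0("ecg_", latents$task)), {
    phi <- stats::runif(1, 0, 2 * pi)
    psi <- stats::runif(1, 0, 2 * pi)
    t <- 0.2
    out <- numeric(0)
    while (t < duration) {
      out <- c(out, t)
      s <- latent_at(latents, "stress", t)
      a_lf <- profile$lf_amp * (1 + profile$lf_gain * s)
      a_hf <- max(profile$hf_amp * (1 - profile$hf_gain * s), 0)
      rr <- profile$rr_mean +
        a_lf * sin(2 * pi * 0.1 * t + phi) +
        a_hf * sin(2 * pi * 0.3 * t + psi) +
        stats::rnorm(1, sd = profile$rr_jitter)
      t <- t + max(rr, 0.3)
    }
    out
  })

  n <- round(duration * fs)
  x <- numeric(n)
  # QRS complex: narrow R peak with Q/S dips, plus a low broad T wave
  tpl_t <- seq(-0.1, 0.35, by = 1 / fs)
  tpl <- 1.0 * exp(-(tpl_t / 0.012)^2) -
    0.15 * exp(-((tpl_t + 0.030) / 0.018)^2) -
    0.20 * exp(-((tpl_t - 0.030) / 0.018)^2) +
    0.25 * exp(-((tpl_t - 0.25) / 0.05)^2)
  off <- which.max(tpl) - 1L
  for (bt in beats) {
    i0 <- round(bt * fs) + 1L - off
    idx <- seq(i0, i0 + length(tpl) - 1L)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl[ok]
  }
  rec <- recording(matrix(x, ncol = 1), fs = fs, channel_names = "ECG",
                   channel_roles = "ECG")
  attr(rec, "ground_truth") <- list(beat_times = beats,
                                    latents = unclass(latents))
  attr(rec, "task") <- latents$task
  rec
}

#' Combine recordings channel-wise
#'
#' Binds recordings sampled at the same rate into one multichannel
#' recording (e.g. EEG plus ECG for a session), truncating to the
#' shortest; ground-truth attributes are merged.
#'
#' @param ... `recording` objects with equal `fs`.
#' @return A `recording`.
#' @export
combine_recordings <- function(...) {
  recs <- list(...)
  stopifnot(length(recs) >= 1)
  fs <- unique(vapply(recs, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) stop("all recordings must share a sampling rate")
  n <- min(vapply(recs, function(r) nrow(r$data), numeric(1)))
  dat <- do.call(cbind, lapply(recs, function(r) r$data[seq_len(n), ,
                                                        drop = FALSE]))
  out <- recording(
    dat, fs = fs,
    channel_names = unlist(lapply(recs, function(r) r$channel_names)),
    channel_roles = unlist(lapply(recs, function(r) r$channel_roles)),
    events = do.call(rbind, lapply(recs, function(r) r$events))
  )
  gts <- lapply(recs, attr, "ground_truth")
  gts <- gts[!vapply(gts, is.null, logical(1))]
  if (length(gts)) {
    attr(out, "ground_truth") <- do.call(c, gts)
  }
  attr(out, "task") <- attr(recs[[1]], "task")
  out
}
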