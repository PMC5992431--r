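#' Synthesize a multichannel EEG recording from latent states
#'
#' Each channel is a sum of six band-limited Gaussian noise carriers (one
#' per EEG band) riding on a 1/f background. The instantaneous amplitude
#' of a carrier is `baseline * (1 + effect * latent(t))` for every row of
#' the profile's effect table whose band and scalp region match, so band
#' powers track the latent states in the configured directions. Optional
#' artifacts (60 Hz line tone, blink-like frontal transients, one
#' high-power bad channel) can be injected; their ground-truth locations
#' are exported with the recording.
#'
#' @param latents a [generate_latents()] trajectory.
#' @param profile a [subject_profile()].
#' @param channels channel labels to synthesize (subset of the montage).
#' @param fs sampling rate in Hz, >= 200 so the 50-100 Hz band fits.
#' @param artifacts `NULL`, or a list with any of `line_amp` (60 Hz tone
#'   amplitude), `blink_rate` (events per minute), `bad_channel` (label).
#' @return A `recording` with EEG roles and an attached `ground_truth`
#'   attribute (latents, injected artifact locations).
#' @export
synthesize_eeg <- function(latents, profile = subject_profile(),
                           channels = profile$channels, fs = 500,
                           artifacts = NULL) {
  bands <- eeg_band_table()
  if (fs < 200) stop("fs must be >= 200 Hz to cover the high-gamma band")
  if (max(bands$hi) > fs / 2) {
    stop("sampling rate too low for requested band (", max(bands$hi),
         " Hz above Nyquist)")
  }
  stopifnot(length(channels) >= 2, all(channels %in% colnames(profile$baseline)))
  duration <- max(latents$times)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  drv <- latent_drives(latents, tt)
  groups <- channel_group(channels)

  dat <- with_seed(child_seed(profile$seed, paste0("eeg_", latents$task)), {
    out <- matrix(0, n, length(channels))
    for (ci in seq_along(channels)) {
      x <- profile$noise_scale * pink_noise(n)
      for (bi in seq_len(nrow(bands))) {
        carrier <- band_limited_noise(n, fs, bands$lo[bi], bands$hi[bi])
        env <- band_envelope(profile, bands$band[bi], channels[ci],
                             groups[ci], drv)
        x <- x + carrier * env
      }
      out[, ci] <- x
    }
    out
  })

  gt_art <- list()
  if (!is.null(artifacts)) {
    if (!is.null(artifacts$line_amp) && artifacts$line_amp > 0) {
      dat <- dat + artifacts$line_amp * sin(2 * pi * 60 * tt)
      gt_art$line_amp <- artifacts$line_amp
    }
    if (!is.null(artifacts$blink_rate) && artifacts$blink_rate > 0) {
      blink_t <- with_seed(child_seed(profile$seed, "blinks"), {
        sort(stats::runif(max(1, round(artifacts$blink_rate * duration / 60)),
                          1, duration - 1))
      })
      front <- which(groups %in% c("pre_frontal", "frontal"))
      if (!length(front)) front <- seq_along(channels)
      shape <- 60 * exp(-((seq(-0.2, 0.2, by = 1 / fs)) / 0.08)^2)
      for (bt in blink_t) {
        i0 <- round(bt * fs) - (length(shape) - 1) %/% 2
        idx <- seq(i0, i0 + length(shape) - 1)
        ok <- idx >= 1 & idx <= n
        # blink projects to anterior channels with decreasing gain
        for (k in seq_along(front)) {
          dat[idx[ok], front[k]] <- dat[idx[ok], front[k]] +
            shape[ok] / k
        }
      }
      gt_art$blink_times <- blink_t
    }
    if (!is.null(artifacts$bad_channel)) {
      bi <- match(artifacts$bad_channel, channels)
      if (is.na(bi)) stop("bad_channel not among synthesized channels")
      dat[, bi] <- dat[, bi] * 8
      gt_art$bad_channel <- artifacts$bad_channel
    }
  }

  rec <- recording(dat, fs = fs, channel_names = channels,
                   channel_roles = rep("EEG", length(channels)))
  attr(rec, "ground_truth") <- list(latents = unclass(latents),
                                    artifacts = gt_art)
  attr(rec, "task") <- latents$task
  rec
}

# Amplitude envelope of one band carrier on one channel.
band_envelope <- function(profile, band, channel, group, drives) {
  base <- profile$baseline[band, channel]
  eff <- profile$effects
  rows <- eff$band == band & (eff$group == "all" | eff$group %in% group)
  mult <- rep(1, nrow(drives))
  if (any(rows)) {
    sub <- eff[rows, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      mult <- mult + sub$effect[i] * drives[, sub$latent[i]]
    }
  }
  base * pmax(mult, 0)
}

# Unit-variance Gaussian noise restricted to [lo, hi) Hz via FFT masking.
band_limited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  X[f < lo | f >= hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# 1/f ("pink") background noise, unit variance, exponent fixed at 1.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  shape <- c(0, 1 / sqrt(f[-1]))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}
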