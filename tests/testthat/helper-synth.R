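# Shared builders for synthetic test cohorts. Sessions are 250 Hz and a
# few minutes long so the suite stays fast; the montage subsets are the
# scalp regions the corresponding effect tables act on.

fatigue_channels <- c("F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
                      "FC6")
frontal_channels <- c("F7", "F3", "Fz", "F4", "F8")
stress_channels <- c("Fp1", "Fp2", "C3", "Cz", "C4", "CP1", "CP2")

# High-SNR fatigue effect table (frontal gamma up, fronto-central alpha
# down with fatigue).
fatigue_effects <- function(gamma = 1.0, alpha = -0.5) {
  rbind(
    data.frame(latent = "fatigue", band = "gamma", group = "frontal",
               effect = gamma),
    data.frame(latent = "fatigue", band = "alpha",
               group = "fronto_central", effect = alpha)
  )
}

# Stress-only effect table (theta up / alpha down over pre-frontal,
# central and centro-parietal sites).
stress_effects <- function(theta = 0.3, alpha = -0.2) {
  rbind(
    data.frame(latent = "stress", band = "theta",
               group = c("pre_frontal", "central", "centro_parietal"),
               effect = theta),
    data.frame(latent = "stress", band = "alpha",
               group = c("pre_frontal", "central", "centro_parietal"),
               effect = alpha)
  )
}

# Synthesize + preprocess one calibration session; returns the recording
# (with beats when ECG is included).
make_session <- function(profile, task, duration, fs = 250, ecg = TRUE,
                         preproc = TRUE) {
  lat <- generate_latents(task, duration, profile)
  rec <- synthesize_eeg(lat, profile, fs = fs)
  if (ecg) rec <- combine_recordings(rec, synthesize_ecg(lat, profile,
                                                         fs = fs))
  if (preproc) rec <- preprocess(rec, run_ica = FALSE)
  attr(rec, "task") <- task
  list(recording = rec, latents = lat,
       beats = if (ecg) detect_r_peaks(rec))
}

# Labeled two-task training features for one biometric; re-keys window
# ids across tasks and computes cardiac features for stress.
make_calib_features <- function(profile, biometric,
                                dur_low = 300, dur_high = 300,
                                fs = 250, ecg = (biometric == "stress")) {
  sb <- make_session(profile, "breath_count", dur_low, fs, ecg)
  s3 <- make_session(profile, "nback3", dur_high, fs, ecg)
  eeg <- rbind(
    training_windows(sb$recording, biometric, "breath_count",
                     channels = profile$channels),
    training_windows(s3$recording, biometric, "nback3",
                     channels = profile$channels)
  )
  key <- paste(eeg$task, eeg$window_id)
  eeg$window_id <- match(key, unique(key))
  ecg_feats <- NULL
  if (ecg) {
    uw <- unique(eeg[, c("window_id", "start", "end", "label", "task")])
    parts <- lapply(split(uw, uw$task), function(u) {
      s <- if (u$task[1] == "breath_count") sb else s3
      cf <- cardiac_window_features(
        s$beats, u[order(u$window_id), ], mode = "Ps2_bands",
        span = c(0, recording_duration(s$recording)))
      cf$window_id <- sort(u$window_id)
      cf
    })
    ecg_feats <- do.call(rbind, parts)
    ecg_feats <- ecg_feats[order(ecg_feats$window_id), ]
  }
  list(eeg = eeg, ecg = ecg_feats, sessions = list(breath_count = sb,
                                                   nback3 = s3))
}

# A plain labeled feature table with no signal synthesis: lognormal
# band powers, optionally with a class effect on chosen bands.
make_feature_table <- function(n_windows, channels = c("F3", "Cz"),
                               effect_bands = character(0),
                               effect_size = 0, seed = 1) {
  bands <- eeg_band_table()$band
  set.seed(seed)
  label <- rep(c("low", "high"), length.out = n_windows)
  rows <- list()
  for (ch in channels) {
    m <- matrix(exp(rnorm(n_windows * length(bands), sd = 0.3)),
                n_windows, length(bands), dimnames = list(NULL, bands))
    for (b in effect_bands) {
      m[, b] <- m[, b] * exp(effect_size * (label == "high"))
    }
    df <- as.data.frame(m)
    df$channel <- ch
    df$window_id <- seq_len(n_windows)
    df$start <- (df$window_id - 1) * 10
    df$end <- df$start + 10
    df$label <- label
    df$task <- "synthetic"
    rows[[ch]] <- df
  }
  do.call(rbind, rows)
}
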