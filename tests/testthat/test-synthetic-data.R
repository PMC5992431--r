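test_that("latent trajectories satisfy their structural invariants", {
  p <- subject_profile(seed = 4)
  for (task in c("breath_count", "nback1", "nback3")) {
    l <- generate_latents(task, 300, p)
    expect_true(all(diff(l$times) > 0))
    expect_true(all(diff(l$fatigue) >= 0))
    expect_true(all(l$fatigue >= 0 & l$fatigue <= 1))
    expect_true(all(l$attention %in% c(0L, 1L)))
    if (task != "breath_count") {
      expect_true(all(l$attention == 1L))
      expect_length(l$mw_events, 0)
    }
  }
  # every button press closes an attention=0 bout
  l <- generate_latents("breath_count", 600, p)
  dt <- l$times[2] - l$times[1]
  for (e in l$mw_events) {
    expect_equal(l$attention[which.min(abs(l$times - (e - dt)))], 0L)
    expect_equal(l$attention[which.min(abs(l$times - (e + 2 * dt)))], 1L)
  }
  expect_error(generate_latents("juggling", 300, p))
  expect_error(generate_latents("nback3", -5, p))
})

test_that("stress levels are strictly ordered breath-count < 1-back < 3-back", {
  p <- subject_profile(seed = 2)
  s <- vapply(c("breath_count", "nback1", "nback3"),
              function(tk) generate_latents(tk, 120, p)$stress[1],
              numeric(1))
  expect_true(s[1] < s[2] && s[2] < s[3])
  # 3-back stress is constant at the high level, no mind-wandering
  l3 <- generate_latents("nback3", 120, p)
  expect_equal(length(unique(l3$stress)), 1L)
})

test_that("identical profile seed reproduces recordings bit-for-bit", {
  p <- subject_profile(seed = 12, channels = c("F3", "Fz", "Cz", "Pz"))
  l <- generate_latents("nback3", 60, p)
  e1 <- synthesize_eeg(l, p, fs = 250)
  e2 <- synthesize_eeg(l, p, fs = 250)
  expect_identical(e1$data, e2$data)
  c1 <- synthesize_ecg(l, p, fs = 250)
  c2 <- synthesize_ecg(l, p, fs = 250)
  expect_identical(c1$data, c2$data)
  # different seed differs
  p2 <- subject_profile(seed = 13, channels = p$channels)
  expect_false(identical(synthesize_eeg(l, p2, fs = 250)$data, e1$data))
})

test_that("EEG band powers are stationary when all effects are zero", {
  p <- subject_profile(seed = 5, channels = c("F3", "Fz", "Cz", "Pz"),
                       effects = default_effect_table()[0, ])
  l <- generate_latents("nback3", 300, p)
  rec <- synthesize_eeg(l, p, fs = 250)
  attr(rec, "task") <- "nback3"
  fe <- test_windows(rec, "fatigue", stride = 10, channels = "F3")
  # no trend: regression of window gamma power on time non-significant
  fit <- summary(lm(gamma ~ center, data = fe))
  expect_gt(fit$coefficients["center", "Pr(>|t|)"], 0.01)
})

test_that("a frontal gamma effect raises late-task gamma power", {
  p <- subject_profile(seed = 6, channels = frontal_channels,
                       effects = fatigue_effects(gamma = 0.5, alpha = 0))
  l <- generate_latents("nback3", 300, p)
  rec <- synthesize_eeg(l, p, fs = 250)
  attr(rec, "task") <- "nback3"
  fe <- test_windows(rec, "fatigue", stride = 10, channels = "F3")
  q <- stats::quantile(fe$center, c(0.25, 0.75))
  early <- fe$gamma[fe$center <= q[1]]
  late <- fe$gamma[fe$center >= q[2]]
  expect_lt(stats::t.test(late, early, alternative = "greater")$p.value,
            0.01)
})

test_that("injected artifacts are constructed as documented", {
  chans <- c("F7", "F3", "Fz", "F4", "F8", "FC1", "FC2", "C3", "Cz",
             "C4", "CP1", "CP2", "P3", "Pz", "P4", "O1")
  p <- subject_profile(seed = 8, channels = chans)
  l <- generate_latents("nback3", 60, p)
  rec <- synthesize_eeg(l, p, fs = 250,
                        artifacts = list(bad_channel = "Cz",
                                         line_amp = 20))
  pow <- vapply(colnames(rec$data), function(ch) {
    band_power(rec$data[, ch], 250, c(1, 125), taper = "rectangular")
  }, numeric(1))
  norm <- log10(pow / median(pow))
  expect_identical(names(which(norm > mean(norm) + 3 * sd(norm))), "Cz")
  # line tone present at 60 Hz
  expect_gt(band_power(rec$data[, "F3"], 250, c(59, 61)),
            band_power(rec$data[, "F3"], 250, c(55, 57)))
  expect_identical(attr(rec, "ground_truth")$artifacts$bad_channel, "Cz")
})

test_that("EEG synthesis rejects impossible sampling rates", {
  p <- subject_profile(seed = 1, channels = c("F3", "Cz"))
  l <- generate_latents("nback3", 30, p)
  expect_error(synthesize_eeg(l, p, fs = 150), "200 Hz")
})

test_that("constant-RR ECG yields the exact beat count and intervals", {
  p <- subject_profile(seed = 3, rr_mean = 1.0, lf_amp = 0, hf_amp = 0,
                       rr_jitter = 0)
  l <- generate_latents("breath_count", 60, p)
  rec <- synthesize_ecg(l, p, fs = 500)
  bt <- attr(rec, "ground_truth")$beat_times
  expect_true(abs(length(bt) - 60) <= 1)
  expect_equal(diff(bt), rep(1.0, length(bt) - 1), tolerance = 1e-12)
})

test_that("HF modulation of RR lands the spectral peak in the HF band", {
  p <- subject_profile(seed = 3, rr_mean = 1.0, lf_amp = 0,
                       hf_amp = 0.05, hf_gain = 0, rr_jitter = 0)
  l <- generate_latents("breath_count", 300, p)
  rec <- synthesize_ecg(l, p, fs = 500)
  bt <- attr(rec, "ground_truth")$beat_times
  bs <- structure(list(peak_times = bt, rr = diff(bt)),
                  class = "beat_series")
  sp <- hrv_spectrum(bs)
  f_peak <- sp$freq[which.max(sp$power)]
  expect_gte(f_peak, 0.15)
  expect_lte(f_peak, 0.4)
})

test_that("a mid-recording stress step raises the late LF/HF ratio", {
  p <- subject_profile(seed = 9, rr_jitter = 0.002, lf_gain = 2,
                       hf_gain = 0.7)
  lat <- generate_latents("breath_count", 600, p)
  lat$stress <- ifelse(lat$times < 300, 0, 1) # explicit step
  rec <- synthesize_ecg(lat, p, fs = 500)
  bt <- attr(rec, "ground_truth")$beat_times
  bs <- structure(list(peak_times = bt, rr = diff(bt)),
                  class = "beat_series")
  lf_hf <- function(win) {
    f <- hrv_band_features(hrv_spectrum(bs, win), "Ps2_bands")
    f["LF"] / f["HF"]
  }
  expect_gt(lf_hf(c(300, 600)), lf_hf(c(0, 300)))
})

test_that("null-mode behavior is independent of the latents", {
  p0 <- subject_profile(seed = 1)
  lat <- generate_latents("threat_detection", 620, p0)
  r <- vapply(1:100, function(s) {
    tr <- synthesize_behavior(lat, p0, n_trials = 200, null_mode = TRUE,
                              seed = 5000 + s)
    lat_f <- stats::approx(lat$times, lat$fatigue, tr$onset + 1)$y
    cor(lat_f, tr$rt)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("linked behavior reaches the designed latent-RT correlation", {
  beh <- list(b0 = 1.2, b = c(fatigue = -1.2, stress = -0.8,
                              mind_wandering = -1.0),
              r0 = 0.6, r = c(fatigue = 0.30, stress = 0.15,
                              mind_wandering = 0.2), rt_sd = 0.12)
  p <- subject_profile(seed = 21, behavior = beh)
  lat <- generate_latents("threat_detection", 620, p)
  tr <- synthesize_behavior(lat, p, n_trials = 200, seed = 42)
  lat_f <- stats::approx(lat$times, lat$fatigue, tr$onset + 1)$y
  r <- cor(lat_f, tr$rt)
  # Fisher-z 99% interval around the designed r ~ 0.5 at n = 200
  expect_gt(r, 0.35)
  expect_lt(r, 0.62)
})

test_that("constant latents leave only the noise variance in RT", {
  beh <- list(b0 = 1.2, b = c(fatigue = 0, stress = 0,
                              mind_wandering = 0),
              r0 = 1.0, r = c(fatigue = 1, stress = 1,
                              mind_wandering = 1), rt_sd = 0.1)
  p <- subject_profile(seed = 31, behavior = beh)
  lat <- generate_latents("breath_count", 4000, p)
  lat$fatigue <- rep(0.3, length(lat$times)) # force constant latents
  lat$stress <- rep(0.3, length(lat$times))
  lat$attention <- rep(1L, length(lat$times))
  tr <- synthesize_behavior(lat, p, n_trials = 1000, seed = 5)
  expect_equal(stats::var(tr$rt), 0.1^2, tolerance = 0.2)
})

test_that("trials that do not fit the latent span are rejected", {
  p <- subject_profile(seed = 1)
  lat <- generate_latents("threat_detection", 60, p)
  expect_error(synthesize_behavior(lat, p, n_trials = 50), "span")
  expect_error(synthesize_behavior(lat, p, n_trials = 5), "n_trials")
})
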