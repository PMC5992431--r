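make_rec <- function(dat, fs = 500, roles = NULL) {
  recording(dat, fs = fs, channel_roles = roles)
}

test_that("basic filters notch 60 Hz, remove DC, and keep a symmetric pair", {
  fs <- 500
  t <- seq(1 / fs, 60, by = 1 / fs)
  tone <- sin(2 * pi * 60 * t)
  x <- cbind(a = tone, b = -tone, c = tone, d = -tone)
  out <- basic_filters(make_rec(x, fs))
  # >= 30 dB steady-state attenuation of the line tone
  expect_lt(sqrt(mean(out$data[, "a"]^2)), 0.032 * sqrt(mean(tone^2)))
  # DC offset removal
  x2 <- cbind(a = rnorm(fs * 20) + 5, b = rnorm(fs * 20) - 3)
  out2 <- basic_filters(make_rec(x2, fs))
  expect_lt(max(abs(colMeans(out2$data))), 1e-6)
  # +x / -x EEG pair: average reference is zero, both unchanged by it
  y <- rnorm(fs * 20)
  rec3 <- make_rec(cbind(a = y, b = -y), fs)
  out3 <- basic_filters(rec3)
  ref_free <- basic_filters(make_rec(cbind(a = y, b = -y), fs,
                                     roles = c("AUX", "AUX")))
  expect_equal(out3$data[, "a"], ref_free$data[, "a"], tolerance = 1e-9)
  expect_error(basic_filters(make_rec(x, fs = 100)), "Nyquist")
})

test_that("channel rejection flags exactly the planted power outliers", {
  fs <- 250
  n <- fs * 30
  set.seed(42)
  base <- matrix(rnorm(n * 29), n, 29)
  colnames(base) <- eeg_montage()$label
  # single 20x-power outlier among equal-power noise
  x <- base
  x[, "T7"] <- x[, "T7"] * 20
  rj <- reject_channels(make_rec(x, fs))
  expect_identical(rj$rejected, "T7")
  # flagged, not dropped
  expect_equal(ncol(rj$recording$data), 29)
  expect_identical(attr(rj$recording, "rejected_channels"), "T7")
  # two planted outliers, both caught in a single pass (oracle: direct
  # mean + 3 SD rule on the log-normalized powers)
  x2 <- base
  x2[, c("T7", "O2")] <- x2[, c("T7", "O2")] * 20
  pow <- vapply(colnames(x2), function(ch) {
    band_power(x2[, ch], fs, c(1, 125), taper = "rectangular")
  }, numeric(1))
  lp <- log10(pow / median(pow))
  oracle <- names(which(lp > mean(lp) + 3 * sd(lp)))
  rj2 <- reject_channels(make_rec(x2, fs))
  expect_setequal(rj2$rejected, c("T7", "O2"))
  expect_setequal(rj2$rejected, oracle)
  # identical channels: none rejected
  same <- matrix(rep(rnorm(n), 4), n, 4)
  colnames(same) <- c("F3", "Fz", "Cz", "Pz")
  expect_length(reject_channels(make_rec(same, fs))$rejected, 0)
  expect_error(reject_channels(make_rec(same[, 1:3], fs)), "4 EEG")
})

test_that("ICA reconstructs the data and separates planted sources", {
  fs <- 250
  n <- fs * 120
  t <- seq_len(n) / fs
  set.seed(7)
  S <- cbind(sin(2 * pi * 1.3 * t), sign(sin(2 * pi * 0.7 * t)),
             rnorm(n))
  A <- matrix(c(1, 0.5, 0.3, 0.4, 1, 0.6, 0.2, 0.3, 1), 3, 3)
  X <- S %*% t(A)
  colnames(X) <- c("F3", "Cz", "Pz")
  rec <- make_rec(X, fs)
  ics <- ica_decompose(rec, seed = 3)
  # mixing . sources reconstructs the data
  expect_equal(ic_reconstruct(ics), X, tolerance = 1e-6,
               ignore_attr = TRUE)
  # each planted source is recovered by some component (|r| ~ 1)
  cors <- abs(cor(S, ics$sources))
  expect_true(all(apply(cors, 1, max) > 0.95))
})

test_that("nuisance ranking orders components by max |r| against nuisance", {
  n <- 30000
  set.seed(11)
  eog <- rnorm(n)
  ecg <- rnorm(n)
  ics <- structure(
    list(sources = cbind(rnorm(n),
                         0.9 * ecg + sqrt(1 - 0.81) * rnorm(n) +
                           0.0 * eog,
                         eog,
                         rep(0, n)),
         mixing = diag(4), means = rep(0, 4),
         channels = paste0("ch", 1:4), noise_rank = NULL,
         rejected = integer(0)),
    class = "ic_decomposition")
  ranked <- rank_noise_components(ics, cbind(eog, ecg))
  # the EOG copy first (|r| ~ 1), the 0.9-ECG component second (max
  # rule: its key is the larger of its two correlations)
  expect_equal(ranked$noise_rank[1:2], c(3L, 2L))
  expect_gt(ranked$rank_key[3], 0.99)
  expect_equal(ranked$rank_key[2], 0.9, tolerance = 0.05)
  # zero-variance component ranks last
  expect_equal(ranked$noise_rank[4], 4L)
  # independent component stays below the null-correlation bound
  expect_lt(ranked$rank_key[1], 0.05)
})

test_that("iterative IC rejection matches a brute-force oracle", {
  fs <- 250
  n <- fs * 60
  t <- seq_len(n) / fs
  set.seed(5)
  # one component carries a 60 Hz tone; the quality index is the
  # fraction of non-physiological power, so only its removal helps
  S <- cbind(10 * sin(2 * pi * 60 * t) + 0.1 * rnorm(n),
             band_limited_noise(n, fs, 4, 8),
             band_limited_noise(n, fs, 8, 12),
             band_limited_noise(n, fs, 13, 30))
  ics <- structure(
    list(sources = S, mixing = diag(4) * 5, means = rep(0, 4),
         channels = c("F3", "Fz", "Cz", "Pz"),
         noise_rank = 1:4, rejected = integer(0)),
    class = "ic_decomposition")
  rec <- make_rec(ic_reconstruct(ics), fs)
  res <- iterative_ic_rejection(ics, rec)
  expect_identical(res$rejected, 1L)
  # brute-force oracle: replay the same visit order and rule
  oracle_rejected <- integer(0)
  qi <- function(drop) {
    sub <- rec
    sub$data <- ic_reconstruct(ics, drop)
    default_quality_index(sub)
  }
  for (comp in 1:4) {
    if (4 - length(oracle_rejected) - 1 < 1) break
    if (qi(c(oracle_rejected, comp)) - qi(oracle_rejected) < -0.001) {
      oracle_rejected <- c(oracle_rejected, comp)
    }
  }
  expect_identical(res$rejected, sort(oracle_rejected))
})

test_that("constant quality index rejects nothing", {
  set.seed(2)
  S <- matrix(rnorm(4000), 1000, 4)
  ics <- structure(
    list(sources = S, mixing = diag(4), means = rep(0, 4),
         channels = c("F3", "Fz", "Cz", "Pz"),
         noise_rank = 1:4, rejected = integer(0)),
    class = "ic_decomposition")
  rec <- make_rec(S, 250)
  res <- iterative_ic_rejection(ics, rec, quality_index = function(r) 1)
  expect_length(res$rejected, 0)
  # non-finite quality index is a pipeline failure naming the component
  expect_error(
    iterative_ic_rejection(ics, rec, quality_index = function(r) NaN),
    class = "pipeline_failure")
})

test_that("spherical interpolation rebuilds a channel from its neighbors", {
  fs <- 250
  n <- fs * 30
  t <- seq_len(n) / fs
  s <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 9 * t)
  chans <- c("FC1", "Cz", "FC2", "Fz", "C3", "C4")
  X <- matrix(rep(s, length(chans)), n, length(chans))
  colnames(X) <- chans
  set.seed(3)
  X <- X + 0.05 * matrix(rnorm(length(X)), nrow(X))
  X[, "Cz"] <- rnorm(n) * 10 # corrupt the channel to interpolate
  rec <- make_rec(X, fs)
  out <- interpolate_and_detrend(rec, rejected = "Cz")
  expect_identical(dim(out$data), dim(X))
  expect_identical(colnames(out$data), chans)
  # detrending removes slow content, so compare to the detrended source
  s_detr <- s - centered_moving_average(s, 1000)
  expect_gt(cor(out$data[, "Cz"], s_detr), 0.95)
})

test_that("moving-average subtraction zeroes constants and kills drift", {
  fs <- 500
  n <- fs * 30
  rec <- make_rec(cbind(a = rep(2.5, n), b = rep(-1, n)), fs)
  out <- interpolate_and_detrend(rec, rejected = character(0))
  expect_equal(max(abs(out$data)), 0)
  # 0.01 Hz ramp on an ECG channel: slope reduced by > 99%
  drift <- 0.05 * seq_len(n) / fs
  rec2 <- recording(cbind(ECG = drift), fs = fs, channel_roles = "ECG")
  out2 <- interpolate_and_detrend(rec2, rejected = character(0))
  core <- (fs * 2):(n - fs * 2) # away from edge shrinkage
  slope <- coef(lm(out2$data[core, 1] ~ seq_along(core)))[2]
  expect_lt(abs(slope), 0.01 * (0.05 / fs))
})

test_that("too few positioned neighbors falls back to inverse-distance", {
  fs <- 250
  n <- fs * 20
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("F3", "F4", "Fz")
  rec <- make_rec(X, fs)
  expect_message(interpolate_and_detrend(rec, rejected = "Fz"),
                 "inverse-distance")
})

test_that("preprocessing is near-idempotent on already-clean data", {
  p <- subject_profile(seed = 17, channels = c("F3", "Fz", "Cz", "Pz"))
  l <- generate_latents("nback3", 120, p)
  rec <- synthesize_eeg(l, p, fs = 250)
  once <- preprocess(rec, run_ica = FALSE)
  twice <- preprocess(once, run_ica = FALSE)
  attr(once, "task") <- attr(twice, "task") <- "nback3"
  f1 <- test_windows(once, "fatigue", stride = 10, channels = "F3")
  f2 <- test_windows(twice, "fatigue", stride = 10, channels = "F3")
  bands <- eeg_band_table()$band
  rel <- abs(as.matrix(f2[, bands]) - as.matrix(f1[, bands])) /
    as.matrix(f1[, bands])
  expect_lt(max(colMeans(rel)), 0.05)
})

test_that("full preprocess removes an injected line artifact via ICA", {
  p <- subject_profile(seed = 23,
                       channels = c("F3", "Fz", "F4", "Cz", "Pz"))
  l <- generate_latents("nback3", 120, p)
  eeg <- synthesize_eeg(l, p, fs = 250)
  # a strong common line tone across channels plus an EOG-like nuisance
  t <- seq_len(nrow(eeg$data)) / 250
  art <- 30 * sin(2 * pi * 47 * t)
  gain <- seq(1, 0.2, length.out = 5)
  eeg$data <- eeg$data + outer(art, gain)
  eog <- recording(cbind(EOG = art + rnorm(length(art))), fs = 250,
                   channel_roles = "EOG")
  rec <- combine_recordings(eeg, eog)
  qi_47 <- function(r) {
    mean(apply(r$data, 2, function(x) {
      band_power(x, r$fs, c(46, 48)) /
        band_power(x, r$fs, c(1, 124.9))
    }))
  }
  out <- preprocess(rec, quality_index = qi_47, run_ica = TRUE, seed = 4)
  rep <- attr(out, "preprocess_report")
  expect_gte(length(rep$rejected_ics), 1)
  p_before <- band_power(rec$data[, "F3"], 250, c(46, 48))
  p_after <- band_power(out$data[, "F3"], 250, c(46, 48))
  expect_lt(p_after, 0.05 * p_before)
})
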