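test_that("feature-set specifications match their definitions", {
  all6 <- eeg_band_table()$band
  expect_equal(feature_set_spec("Pf1")$eeg_bands, c("theta", "alpha"))
  expect_equal(feature_set_spec("Pf2")$eeg_bands, all6)
  expect_equal(feature_set_spec("Ps3")$eeg_bands, all6)
  expect_equal(feature_set_spec("Pa3")$eeg_bands,
               c("delta", "theta", "alpha", "beta"))
  expect_equal(feature_set_spec("Pa1")$ratio, c("theta", "beta"))
  expect_identical(feature_set_spec("Ps1")$source, "ECG_only")
  expect_identical(feature_set_spec("Ps2")$source, "ECG_only")
  for (id in c("Pf1", "Pf2", "Ps1", "Ps2", "Ps3", "Ps4")) {
    expect_equal(feature_set_spec(id)$window, 10)
  }
  for (id in c("Pa1", "Pa2", "Pa3")) {
    expect_equal(feature_set_spec(id)$window, 6)
  }
  expect_error(feature_set_spec("Px9"))
})

test_that("design assembly implements ratios, Ps4 width, and guards", {
  fe <- make_feature_table(20, channels = "F3")
  fe$theta <- 4
  fe$beta <- 2
  d <- assemble_design(fe, NULL, feature_set_spec("Pa1"), "F3",
                       transform = "raw")
  expect_equal(unname(d$X[, 1]), rep(2, 20)) # theta/beta ratio
  expect_equal(ncol(d$X), 1)
  # Ps4 has exactly 9 columns: 6 EEG bands + 3 HRV bands
  ecg <- data.frame(window_id = 1:20, start = 0, end = 10,
                    VLF = 1, LF = 2, HF = 3, missing = FALSE,
                    label = fe$label[1:20])
  d4 <- assemble_design(fe, ecg, feature_set_spec("Ps4"), "F3",
                        transform = "raw")
  expect_equal(ncol(d4$X), 9)
  # zero denominator guarded by epsilon, with a message
  fe$beta <- 0
  expect_message(
    dg <- assemble_design(fe, NULL, feature_set_spec("Pa1"), "F3",
                          transform = "raw"),
    "epsilon")
  expect_true(all(is.finite(dg$X)))
  # rows with missing cardiac features are dropped
  ecg$VLF[3] <- NA
  d5 <- assemble_design(fe, ecg, feature_set_spec("Ps4"), "F3",
                        transform = "raw")
  expect_equal(nrow(d5$X), 19)
})

test_that("the ridge-IRLS GLM matches its oracles", {
  # balanced labels with a single all-zero feature: intercept 0,
  # prediction exactly 0.5
  X <- matrix(0, 100, 1)
  y <- rep(c(0, 1), 50)
  fit <- fit_glm(X, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[1]), 1e-6)
  expect_equal(predict(fit, X)[1], 0.5, tolerance = 1e-6)
  # 1-D logistic recovery vs the unpenalized likelihood maximized by
  # stats::glm (the independent route)
  set.seed(33)
  x <- rnorm(2000)
  yy <- rbinom(2000, 1, plogis(0.5 + 1.5 * x))
  mine <- fit_glm(matrix(x, ncol = 1), yy)
  ref <- glm(yy ~ x, family = binomial())
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-3)
  # Wald inference agrees with the reference fit too
  expect_equal(unname(mine$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-2)
  # perfectly separable data: the ridge keeps coefficients finite and
  # preserves the score ordering
  xs <- c(rep(-1, 25), rep(1, 25))
  ys <- c(rep(0, 25), rep(1, 25))
  sep <- fit_glm(matrix(xs, ncol = 1), ys)
  expect_true(all(is.finite(sep$coef)))
  pr <- predict(sep, matrix(c(-2, 0, 2), ncol = 1))
  expect_true(all(diff(pr) > 0))
  expect_error(fit_glm(matrix(0, 10, 1), rep(1, 10)), "classes")
  expect_error(fit_glm(matrix(rnorm(4), 2, 2), c(0, 1)), "rows")
})

test_that("committees have one member per electrode and average outputs", {
  fe <- make_feature_table(40, channels = c("F3", "Cz"),
                           effect_bands = "gamma", effect_size = 2,
                           seed = 2)
  cm <- train_committee(fe, NULL, "Pf2")
  expect_length(cm$members, 2)
  expect_setequal(names(cm$members), c("F3", "Cz"))
  # ECG-only: exactly one member
  ecg <- data.frame(window_id = 1:40, start = 0, end = 10,
                    VLF = exp(rnorm(40)), LF = exp(rnorm(40)),
                    HF = exp(rnorm(40) + 2 * (fe$label[1:40] == "high")),
                    missing = FALSE, label = fe$label[1:40])
  cm2 <- train_committee(NULL, ecg, "Ps2")
  expect_length(cm2$members, 1)
  # the committee value is the plain mean of member outputs
  fake <- cm
  for (i in seq_along(fake$members)) {
    fake$members[[i]]$coef[] <- 0
  }
  fake$members[[1]]$coef["(Intercept)"] <- qlogis(0.2)
  fake$members[[2]]$coef["(Intercept)"] <- qlogis(0.9)
  pred <- mentalstate:::committee_predict_windows(fake, fe, NULL)
  expect_equal(pred$value, rep(mean(c(0.2, 0.9)), 40), tolerance = 1e-12)
})

test_that("committee predictions are invariant to electrode order", {
  fe <- make_feature_table(60, channels = c("F3", "Cz", "Pz"),
                           effect_bands = "theta", effect_size = 1.5,
                           seed = 3)
  cm <- train_committee(fe, NULL, "Pf2")
  cm_rev <- cm
  cm_rev$members <- rev(cm_rev$members)
  a <- mentalstate:::committee_predict_windows(cm, fe, NULL)
  b <- mentalstate:::committee_predict_windows(cm_rev, fe, NULL)
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("a trained committee tracks the latent fatigue ramp", {
  p <- subject_profile(seed = 7, channels = frontal_channels,
                       effects = fatigue_effects(), noise_scale = 2)
  f <- make_calib_features(p, "fatigue", dur_high = 400)
  cm <- train_committee(f$eeg, NULL, "Pf2")
  r3 <- f$sessions$nback3$recording
  tr <- predict_trace(cm, r3)
  expect_true(all(tr$values >= 0 & tr$values <= 1))
  expect_equal(diff(tr$times), rep(1, length(tr$times) - 1))
  gtl <- attr(r3, "ground_truth")$latents
  lat <- approx(gtl$times, gtl$fatigue, xout = tr$times)$y
  expect_gte(cor(tr$values, lat), 0.8)
})

test_that("feature consistency flags the simulated direction and nothing else", {
  # constructive cohort: strong gamma effect on every subject
  models <- lapply(1:4, function(s) {
    fe <- make_feature_table(120, channels = c("F3", "Fz"),
                             effect_bands = "gamma", effect_size = 0.5,
                             seed = 50 + s)
    train_committee(fe, NULL, "Pf2")
  })
  tab <- feature_consistency(models)
  expect_true(all(c("F3", "Fz") %in%
                    tab$channel[tab$feature == "gamma" &
                                  tab$direction == "+"]))
  # null cohort: expected row count bounded by the type-I budget
  null_models <- lapply(1:6, function(s) {
    fe <- make_feature_table(80, channels = c("F3", "Fz"),
                             seed = 100 + s)
    train_committee(fe, NULL, "Pf2")
  })
  null_tab <- feature_consistency(null_models)
  # 2 channels x 6 bands cells; requiring >50% of 6 subjects significant
  # at 0.05 with one sign is rare under the null
  expect_lte(nrow(null_tab), 1)
  expect_error(feature_consistency(models[1]), "2 subjects")
})
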