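#' Feature-set specifications for the nine biometric models
#'
#' The two fatigue, four stress and three attention feature sets:
#' \describe{
#'   \item{Pf1}{EEG theta + alpha band power (10 s windows).}
#'   \item{Pf2}{EEG power in all six bands, delta through high-gamma.}
#'   \item{Ps1}{HRV spectral power in 0.1 Hz bins over 0.01-0.4 Hz
#'     (ECG only, a single non-committee model).}
#'   \item{Ps2}{HRV power in VLF/LF/HF bands (ECG only).}
#'   \item{Ps3}{EEG power in all six bands.}
#'   \item{Ps4}{Ps2 + Ps3: each electrode's six EEG band powers plus the
#'     shared three HRV band powers (9 features).}
#'   \item{Pa1}{theta/beta power ratio, a single feature (6 s windows).}
#'   \item{Pa2}{EEG power in all six bands (6 s windows).}
#'   \item{Pa3}{EEG power in delta, theta, alpha, beta (6 s windows).}
#' }
#' EEG-based sets are trained per electrode and aggregated as a committee
#' mean; ECG-only sets have a single member.
#'
#' @param id one of `"Pf1"`, `"Pf2"`, `"Ps1"`, `"Ps2"`, `"Ps3"`, `"Ps4"`,
#'   `"Pa1"`, `"Pa2"`, `"Pa3"`.
#' @return A `feature_set_spec` list: `id`, `biometric`, `source`,
#'   `eeg_bands`, `ratio`, `ecg_mode`, `window`.
#' @export
feature_set_spec <- function(id) {
  id <- match.arg(id, c("Pf1", "Pf2", "Ps1", "Ps2", "Ps3", "Ps4",
                        "Pa1", "Pa2", "Pa3"))
  all6 <- eeg_band_table()$band
  def <- switch(id,
    Pf1 = list(biometric = "fatigue", source = "EEG_committee",
               eeg_bands = c("theta", "alpha")),
    Pf2 = list(biometric = "fatigue", source = "EEG_committee",
               eeg_bands = all6),
    Ps1 = list(biometric = "stress", source = "ECG_only",
               ecg_mode = "Ps1_bins"),
    Ps2 = list(biometric = "stress", source = "ECG_only",
               ecg_mode = "Ps2_bands"),
    Ps3 = list(biometric = "stress", source = "EEG_committee",
               eeg_bands = all6),
    Ps4 = list(biometric = "stress", source = "EEG_plus_ECG",
               eeg_bands = all6, ecg_mode = "Ps2_bands"),
    Pa1 = list(biometric = "attention", source = "EEG_committee",
               ratio = c("theta", "beta")),
    Pa2 = list(biometric = "attention", source = "EEG_committee",
               eeg_bands = all6),
    Pa3 = list(biometric = "attention", source = "EEG_committee",
               eeg_bands = c("delta", "theta", "alpha", "beta"))
  )
  def$id <- id
  def$window <- if (def$biometric == "attention") 6 else 10
  def$eeg_bands <- def$eeg_bands %||% character(0)
  def$ratio <- def$ratio %||% NULL
  def$ecg_mode <- def$ecg_mode %||% NULL
  structure(def, class = "feature_set_spec")
}

label_to_y <- function(label) {
  y <- rep(NA_integer_, length(label))
  y[label %in% c("low", "inattentive")] <- 0L
  y[label %in% c("high", "attentive")] <- 1L
  y
}

#' Assemble a design matrix for one electrode and feature set
#'
#' Builds `X` (one row per labeled window) and `y` (low/inattentive = 0,
#' high/attentive = 1) following the feature set: band-power columns for
#' the spec's bands, the theta/beta ratio for Pa1 (guarded by a 1e-12
#' denominator floor), HRV columns for ECG-based sets, and for Ps4 the
#' electrode's six EEG bands plus the shared HRV bands. Rows with missing
#' cardiac features are dropped. Features are transformed
#' `log10(x + 1e-12)` and z-scored; standardization statistics are taken
#' from `train_stats` when supplied (prediction) or computed and returned
#' (training).
#'
#' @param eeg_features feature table from [training_windows()],
#'   [attention_windows()] or [test_windows()] (may be `NULL` for
#'   ECG-only sets).
#' @param ecg_features table from [cardiac_window_features()] (needed for
#'   ECG-based sets).
#' @param spec a [feature_set_spec()].
#' @param channel electrode label (ignored for ECG-only sets).
#' @param transform `"log_z"` (default) or `"raw"`.
#' @param train_stats list(mean, sd) from a previous training call.
#' @return list with `X`, `y` (NA for unlabeled windows), `window_id`,
#'   `stats`.
#' @export
assemble_design <- function(eeg_features = NULL, ecg_features = NULL, spec,
                            channel = NULL, transform = c("log_z", "raw"),
                            train_stats = NULL) {
  transform <- match.arg(transform)
  eps <- 1e-12
  if (spec$source != "ECG_only") {
    stopifnot(!is.null(eeg_features), !is.null(channel))
    rows <- eeg_features[eeg_features$channel == channel, , drop = FALSE]
    rows <- rows[order(rows$window_id), , drop = FALSE]
    if (!is.null(spec$ratio)) {
      num <- rows[[spec$ratio[1]]]
      den <- rows[[spec$ratio[2]]]
      if (any(den <= 0)) {
        message("non-positive denominator band power; ratio guarded by epsilon")
      }
      X <- matrix(num / pmax(den, eps), ncol = 1,
                  dimnames = list(NULL, paste(spec$ratio, collapse = "_over_")))
    } else {
      X <- as.matrix(rows[, spec$eeg_bands, drop = FALSE])
    }
    label <- rows$label
    window_id <- rows$window_id
  } else {
    X <- NULL
    label <- NULL
    window_id <- NULL
  }
  if (!is.null(spec$ecg_mode)) {
    stopifnot(!is.null(ecg_features))
    nm <- if (spec$ecg_mode == "Ps2_bands") hrv_band_table()$band else
      paste0("bin", 1:4)
    ecg <- ecg_features[order(ecg_features$window_id), , drop = FALSE]
    H <- as.matrix(ecg[, nm, drop = FALSE])
    if (is.null(X)) {
      X <- H
      label <- if ("label" %in% names(ecg)) ecg$label else
        rep("unlabeled", nrow(H))
      window_id <- ecg$window_id
    } else {
      m <- match(window_id, ecg$window_id)
      X <- cbind(X, H[m, , drop = FALSE])
    }
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  label <- label[keep]
  window_id <- window_id[keep]
  y <- label_to_y(label)
  if (transform == "log_z") {
    X <- log10(X + eps)
    if (is.null(train_stats)) {
      mu <- colMeans(X)
      sd <- apply(X, 2, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
      train_stats <- list(mean = mu, sd = sd)
    }
    X <- sweep(sweep(X, 2, train_stats$mean), 2, train_stats$sd, `/`)
  }
  list(X = X, y = y, window_id = window_id, stats = train_stats)
}

#' Fit a binomial-logit GLM by penalized IRLS
#'
#' Maximizes the binomial log-likelihood with a logit link via
#' iteratively reweighted least squares, with a small ridge penalty on
#' the slopes (not the intercept) that bounds the coefficients on
#' separable data without perceptibly moving non-degenerate fits.
#' Convergence when the largest coefficient change falls below `tol`;
#' non-convergent fits are flagged (and excluded from committees by the
#' callers). Wald standard errors and p-values come from the penalized
#' information matrix.
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param y 0/1 response; both classes must be present and
#'   `nrow(X) > ncol(X)`.
#' @param ridge penalty on slopes (default 1e-4).
#' @param maxit,tol IRLS controls (100 iterations, 1e-8).
#' @return An `electrode_model`: `coef` (intercept first), `se`, `p`,
#'   `converged`, `iterations`.
#' @export
fit_glm <- function(X, y, ridge = 1e-4, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (nrow(X) <= ncol(X)) stop("need more rows than features")
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  D <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- rep(0, p)
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xd %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd, Xd * w) + D
    b <- crossprod(Xd, w * z)
    beta_new <- tryCatch(as.vector(solve(A, b)), error = function(e) NULL)
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  names(beta) <- colnames(Xd)
  eta <- as.vector(Xd %*% beta)
  mu <- sigmoid(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- tryCatch(solve(crossprod(Xd, Xd * w) + D),
                  error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(cov), 0))
  zval <- beta / se
  structure(
    list(coef = beta, se = stats::setNames(se, names(beta)),
         p = stats::setNames(2 * stats::pnorm(-abs(zval)), names(beta)),
         converged = converged, iterations = it),
    class = "electrode_model"
  )
}

#' @export
predict.electrode_model <- function(object, newdata, ...) {
  Xd <- cbind(1, as.matrix(newdata))
  sigmoid(as.vector(Xd %*% object$coef))
}

#' Train a committee of per-electrode GLMs
#'
#' Fits one binomial-logit GLM per retained EEG electrode (a single
#' model for ECG-only sets); predictions are later aggregated as the
#' mean of the member outputs. Per-member training standardization is
#' stored with each member. Electrodes whose fit does not converge are
#' dropped with a warning; training fails only if no member converges.
#'
#' @param eeg_features labeled feature table (training or attention
#'   windows); `NULL` for ECG-only sets.
#' @param ecg_features labeled cardiac feature table for ECG-based sets.
#' @param spec a [feature_set_spec()] or its id string.
#' @param ridge,transform passed to [assemble_design()] / [fit_glm()].
#' @return A `committee_model`: `spec`, `members` (named list of
#'   electrode models with `stats`), `aggregation = "mean"`.
#' @export
train_committee <- function(eeg_features = NULL, ecg_features = NULL, spec,
                            ridge = 1e-4, transform = "log_z") {
  if (is.character(spec)) spec <- feature_set_spec(spec)
  channels <- if (spec$source == "ECG_only") "ECG" else
    unique(eeg_features$channel)
  members <- list()
  for (ch in channels) {
    dsn <- assemble_design(eeg_features, ecg_features, spec,
                           channel = if (ch == "ECG") NULL else ch,
                           transform = transform)
    ok <- !is.na(dsn$y)
    if (!length(unique(dsn$y[ok])) == 2) {
      stop("zero labeled windows of one class for channel ", ch)
    }
    fit <- fit_glm(dsn$X[ok, , drop = FALSE], dsn$y[ok], ridge = ridge)
    if (!fit$converged) {
      warning("electrode ", ch, " did not converge; excluded from committee")
      next
    }
    fit$channel <- ch
    fit$stats <- dsn$stats
    members[[ch]] <- fit
  }
  if (!length(members)) {
    stop_mentalstate("all committee members failed to converge",
                     "pipeline_failure")
  }
  structure(
    list(spec = spec, members = members, aggregation = "mean",
         transform = transform),
    class = "committee_model"
  )
}

#' @export
print.committee_model <- function(x, ...) {
  cat(sprintf("<committee_model> %s (%s): %d member(s)\n",
              x$spec$id, x$spec$biometric, length(x$members)))
  invisible(x)
}

# Committee prediction for a set of windows given precomputed feature
# tables. Returns data.frame(window_id, value).
committee_predict_windows <- function(model, eeg_features = NULL,
                                      ecg_features = NULL) {
  preds <- NULL
  ids <- NULL
  for (m in model$members) {
    dsn <- assemble_design(eeg_features, ecg_features, model$spec,
                           channel = if (m$channel == "ECG") NULL else
                             m$channel,
                           transform = model$transform,
                           train_stats = m$stats)
    p <- predict(m, dsn$X)
    if (is.null(preds)) {
      preds <- p
      ids <- dsn$window_id
    } else {
      preds <- preds + p[match(ids, dsn$window_id)]
    }
  }
  data.frame(window_id = ids, value = preds / length(model$members))
}

#' Predict a biometric trace over a recording
#'
#' Slides the feature-set's test window (10 s for fatigue/stress, 6 s
#' for attention) at a 1 s stride over the recording, evaluates every
#' committee member, and averages the member sigmoids into a single
#' \[0,1\] score per window. The trace timestamp is the window center.
#'
#' @param model a `committee_model`.
#' @param rec a cleaned `recording` longer than the model window.
#' @param beats optional `beat_series` for ECG-based sets (detected from
#'   the recording's ECG channel when omitted).
#' @param hrv_context context length for cardiac features (s).
#' @return A `biometric_trace`: list with `times` (s, 1 s stride) and
#'   `values` in \[0,1\].
#' @export
predict_trace <- function(model, rec, beats = NULL, hrv_context = 120) {
  spec <- model$spec
  eeg_feats <- NULL
  ecg_feats <- NULL
  member_channels <- setdiff(names(model$members), "ECG")
  if (spec$source != "ECG_only") {
    eeg_feats <- test_windows(rec, spec$biometric,
                              channels = member_channels)
  }
  if (!is.null(spec$ecg_mode)) {
    if (is.null(beats)) beats <- detect_r_peaks(rec)
    windows <- if (!is.null(eeg_feats)) {
      unique(eeg_feats[, c("window_id", "start", "end")])
    } else {
      dur <- recording_duration(rec)
      starts <- seq(0, dur - spec$window, by = 1)
      data.frame(window_id = seq_along(starts), start = starts,
                 end = starts + spec$window)
    }
    ecg_feats <- cardiac_window_features(beats, windows, spec$ecg_mode,
                                         context = hrv_context,
                                         span = c(0, recording_duration(rec)))
  }
  pred <- committee_predict_windows(model, eeg_feats, ecg_feats)
  starts <- if (!is.null(eeg_feats)) {
    u <- unique(eeg_feats[, c("window_id", "start", "end")])
    u[match(pred$window_id, u$window_id), ]
  } else {
    windows[match(pred$window_id, windows$window_id), ]
  }
  structure(
    list(times = (starts$start + starts$end) / 2, values = pred$value,
         biometric = spec$biometric, feature_set = spec$id),
    class = "biometric_trace"
  )
}

#' @export
print.biometric_trace <- function(x, ...) {
  cat(sprintf("<biometric_trace> %s (%s): %d points, mean %.3f\n",
              x$biometric, x$feature_set, length(x$values),
              mean(x$values)))
  invisible(x)
}

#' Cross-subject feature-consistency table
#'
#' Screens per-electrode GLM coefficients across subjects: a (channel,
#' band) pair is reported when its coefficient is significant (Wald
#' p < 0.05) with the same sign in more than half of the subjects. This
#' is the interpretability analysis that identifies, e.g., frontal gamma
#' as a consistent positive influence on the fatigue score.
#'
#' @param subject_models list (length >= 2) of `committee_model`s, one
#'   per subject, all for the same feature set.
#' @param alpha per-coefficient significance level.
#' @param min_fraction consistency threshold (fraction of subjects).
#' @return data.frame with `channel`, `feature`, `direction`
#'   (`"+"`/`"-"`), `fraction`.
#' @export
feature_consistency <- function(subject_models, alpha = 0.05,
                                min_fraction = 0.5) {
  if (length(subject_models) < 2) {
    stop("feature consistency needs at least 2 subjects")
  }
  chans <- unique(unlist(lapply(subject_models,
                                function(m) names(m$members))))
  out <- list()
  for (ch in chans) {
    feats <- NULL
    for (m in subject_models) {
      if (!is.null(m$members[[ch]])) {
        feats <- union(feats, setdiff(names(m$members[[ch]]$coef),
                                      "(Intercept)"))
      }
    }
    for (f in feats) {
      sig_pos <- sig_neg <- 0
      n <- 0
      for (m in subject_models) {
        mm <- m$members[[ch]]
        if (is.null(mm) || !(f %in% names(mm$coef))) next
        n <- n + 1
        if (is.finite(mm$p[f]) && mm$p[f] < alpha) {
          if (mm$coef[f] > 0) sig_pos <- sig_pos + 1 else
            sig_neg <- sig_neg + 1
        }
      }
      if (n == 0) next
      if (sig_pos / n > min_fraction) {
        out[[length(out) + 1]] <- data.frame(
          channel = ch, feature = f, direction = "+",
          fraction = sig_pos / n)
      } else if (sig_neg / n > min_fraction) {
        out[[length(out) + 1]] <- data.frame(
          channel = ch, feature = f, direction = "-",
          fraction = sig_neg / n)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(channel = character(0), feature = character(0),
                      direction = character(0), fraction = numeric(0)))
  }
  do.call(rbind, out)
}
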