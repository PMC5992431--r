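#' Balanced fold assignment
#'
#' Splits labeled rows into `k` disjoint folds with an equal number of
#' rows per class in every fold (a uniform class prior). Surplus rows
#' that cannot be balanced are discarded at random under the given seed
#' and get fold `NA`.
#'
#' @param y class labels (any type with exactly 2+ distinct values).
#' @param k number of folds.
#' @param seed RNG seed for the shuffle and surplus discarding.
#' @return Integer vector of fold assignments in `1..k` (`NA` =
#'   discarded), one per element of `y`.
#' @export
balanced_partitions <- function(y, k, seed = 1) {
  classes <- unique(y[!is.na(y)])
  counts <- vapply(classes, function(cl) sum(y == cl, na.rm = TRUE),
                   numeric(1))
  if (min(counts) < k) {
    stop("smallest class has ", min(counts),
         " rows; balanced ", k, "-fold partitioning needs at least ", k)
  }
  per_class <- k * floor(min(counts) / k)
  fold <- rep(NA_integer_, length(y))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(!is.na(y) & y == cl))
      keep <- idx[seq_len(per_class)]
      fold[keep] <- rep(seq_len(k), each = per_class / k)
    }
  })
  fold
}

# Raw (untransformed) per-channel designs for a feature set, keyed by
# channel; shared by the CV and LOO routines.
per_channel_designs <- function(eeg_features, ecg_features, spec) {
  channels <- if (spec$source == "ECG_only") "ECG" else
    unique(eeg_features$channel)
  out <- list()
  for (ch in channels) {
    out[[ch]] <- assemble_design(eeg_features, ecg_features, spec,
                                 channel = if (ch == "ECG") NULL else ch,
                                 transform = "raw")
  }
  out
}

log_z <- function(X, stats = NULL) {
  X <- log10(X + 1e-12)
  if (is.null(stats)) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    stats <- list(mean = mu, sd = sd)
  }
  list(X = sweep(sweep(X, 2, stats$mean), 2, stats$sd, `/`),
       stats = stats)
}

#' Balanced k-fold cross-validation of a feature set
#'
#' Partitions the labeled windows into balanced folds, then for every
#' electrode independently trains the GLM on k-1 folds and scores
#' classification accuracy (threshold 0.5) on the held-out fold.
#' Standardization is refit on each training split. The subject-level
#' accuracy is the mean over channels and folds. Use `k = 10` for
#' fatigue/stress and `k = 3` for attention (mind-wandering event counts
#' are small).
#'
#' @param eeg_features labeled feature table (`NULL` for ECG-only sets).
#' @param ecg_features labeled cardiac features for ECG-based sets.
#' @param spec a [feature_set_spec()] or id string.
#' @param k number of folds.
#' @param seed partition seed.
#' @param ridge GLM ridge penalty.
#' @param transform `"log_z"` or `"raw"`.
#' @return A `cv_result`: `accuracy` (channels x folds matrix),
#'   `subject_accuracy`, `fold` assignment, `spec`.
#' @export
kfold_cv <- function(eeg_features = NULL, ecg_features = NULL, spec,
                     k = 10, seed = 1, ridge = 1e-4,
                     transform = c("log_z", "raw")) {
  transform <- match.arg(transform)
  if (is.character(spec)) spec <- feature_set_spec(spec)
  designs <- per_channel_designs(eeg_features, ecg_features, spec)
  d1 <- designs[[1]]
  fold <- balanced_partitions(d1$y, k, seed)
  acc <- matrix(NA_real_, length(designs), k,
                dimnames = list(names(designs), NULL))
  for (ch in names(designs)) {
    d <- designs[[ch]]
    stopifnot(identical(d$window_id, d1$window_id))
    for (f in seq_len(k)) {
      tr <- which(!is.na(fold) & fold != f)
      te <- which(fold == f)
      if (transform == "log_z") {
        tz <- log_z(d$X[tr, , drop = FALSE])
        Xtr <- tz$X
        Xte <- log_z(d$X[te, , drop = FALSE], tz$stats)$X
      } else {
        Xtr <- d$X[tr, , drop = FALSE]
        Xte <- d$X[te, , drop = FALSE]
      }
      fit <- fit_glm(Xtr, d$y[tr], ridge = ridge)
      pred <- predict(fit, Xte) >= 0.5
      acc[ch, f] <- mean(pred == (d$y[te] == 1))
    }
  }
  structure(
    list(spec = spec, accuracy = acc, fold = fold,
         subject_accuracy = mean(acc)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: accuracy %.3f (%d channels x %d folds)\n",
              x$spec$id, x$subject_accuracy, nrow(x$accuracy),
              ncol(x$accuracy)))
  invisible(x)
}

#' Leave-one-out score bounds
#'
#' Scores every labeled window with a committee trained on all other
#' windows; the mean committee score over low-class windows is the lower
#' bound of the biometric's operating range and the mean over high-class
#' windows the upper bound. An intermediate task's score is expected to
#' fall between them.
#'
#' @param eeg_features,ecg_features labeled feature tables.
#' @param spec a [feature_set_spec()] or id string.
#' @param ridge GLM ridge penalty.
#' @param transform `"log_z"` or `"raw"`.
#' @return list with `low_bound`, `high_bound`, and `scores`
#'   (data.frame window_id, y, score).
#' @export
loo_bounds <- function(eeg_features = NULL, ecg_features = NULL, spec,
                       ridge = 1e-4, transform = c("log_z", "raw")) {
  transform <- match.arg(transform)
  if (is.character(spec)) spec <- feature_set_spec(spec)
  designs <- per_channel_designs(eeg_features, ecg_features, spec)
  d1 <- designs[[1]]
  n <- length(d1$y)
  if (sum(d1$y == 0, na.rm = TRUE) < 10 || sum(d1$y == 1, na.rm = TRUE) < 10) {
    stop("leave-one-out bounds need at least 10 windows per class")
  }
  score <- rep(0, n)
  for (ch in names(designs)) {
    d <- designs[[ch]]
    for (i in seq_len(n)) {
      tr <- setdiff(which(!is.na(d$y)), i)
      if (transform == "log_z") {
        tz <- log_z(d$X[tr, , drop = FALSE])
        Xtr <- tz$X
        Xte <- log_z(d$X[i, , drop = FALSE], tz$stats)$X
      } else {
        Xtr <- d$X[tr, , drop = FALSE]
        Xte <- d$X[i, , drop = FALSE]
      }
      fit <- fit_glm(Xtr, d$y[tr], ridge = ridge)
      score[i] <- score[i] + predict(fit, Xte)
    }
  }
  score <- score / length(designs)
  list(
    low_bound = mean(score[d1$y == 0], na.rm = TRUE),
    high_bound = mean(score[d1$y == 1], na.rm = TRUE),
    scores = data.frame(window_id = d1$window_id, y = d1$y, score = score)
  )
}

#' Paired t-test
#'
#' Thin wrapper around [stats::t.test()] for paired samples, returning a
#' degenerate-flagged result instead of an error when the differences
#' have zero variance.
#'
#' @param a,b paired numeric vectors of equal length >= 3.
#' @param tails `"two"`, `"greater"` (a > b) or `"less"`.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(a, b, tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  stopifnot(length(a) == length(b), length(a) >= 3,
            !anyNA(a), !anyNA(b))
  alt <- switch(tails, two = "two.sided", greater = "greater",
                less = "less")
  if (all(a == b)) {
    # no difference anywhere: t is 0 by convention
    return(list(t = 0, p = if (tails == "two") 1 else 0.5,
                df = length(a) - 1, degenerate = FALSE))
  }
  res <- tryCatch(stats::t.test(a, b, paired = TRUE, alternative = alt),
                  error = function(e) NULL)
  if (is.null(res)) {
    # zero-variance non-zero differences: p undefined
    return(list(t = NA_real_, p = NA_real_, df = length(a) - 1,
                degenerate = TRUE))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), degenerate = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Tests a within-subject factor (time bin) on a subjects-by-bins matrix
#' of scores using `aov` with a subject error stratum.
#'
#' @param mat numeric matrix, one row per subject, one column per time
#'   bin; no missing values.
#' @return list with `F`, `p`, `df`, `degenerate`.
#' @export
repeated_measures_anova <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2, !anyNA(mat))
  df <- data.frame(
    value = as.vector(mat),
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    bin = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  dfs <- c(ncol(mat) - 1, (nrow(mat) - 1) * (ncol(mat) - 1))
  if (stats::sd(df$value) == 0) {
    return(list(F = 0, p = NA_real_, df = dfs, degenerate = TRUE))
  }
  # no between-bin variation at all (identical columns): F is exactly 0
  if (stats::sd(colMeans(mat)) < 1e-12 * stats::sd(mat)) {
    return(list(F = 0, p = 1, df = dfs, degenerate = FALSE))
  }
  fit <- stats::aov(value ~ bin + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  list(F = tab["bin", "F value"], p = tab["bin", "Pr(>F)"],
       df = c(tab["bin", "Df"], tab["Residuals", "Df"]),
       degenerate = FALSE)
}

#' Intermediate-task regression test across subjects
#'
#' Level-2 validation: given per-subject leave-one-out bounds (from the
#' low and high calibration tasks) and per-subject mean scores on the
#' held-out intermediate task (1-back), tests that the intermediate
#' score lies between the bounds with two directional paired t-tests
#' (each at the 0.025 level after correcting for the two comparisons),
#' and tests for a time effect in the intermediate trace with a one-way
#' repeated-measures ANOVA over time-binned trace values (expected
#' present for fatigue, whose latent ramps, and absent for stress, whose
#' latent is flat).
#'
#' @param bounds data.frame with one row per subject and columns
#'   `low_bound`, `high_bound`, `intermediate_score`.
#' @param traces optional list of `biometric_trace`s (one per subject,
#'   the intermediate-task trace) for the time-effect ANOVA.
#' @param n_bins number of time bins for the ANOVA.
#' @param tails `"greater"` for directional tests (default), `"two"`.
#' @return A `regression_report`: mean bounds and intermediate score,
#'   `t_low`, `t_high`, `time_effect`, and the per-subject table.
#' @export
intermediate_regression_test <- function(bounds, traces = NULL,
                                         n_bins = 10,
                                         tails = c("greater", "two")) {
  tails <- match.arg(tails)
  stopifnot(all(c("low_bound", "high_bound", "intermediate_score") %in%
                  names(bounds)))
  out <- list(
    low_bound = mean(bounds$low_bound),
    high_bound = mean(bounds$high_bound),
    intermediate_score = mean(bounds$intermediate_score),
    n_subjects = nrow(bounds),
    per_subject = bounds
  )
  if (nrow(bounds) >= 2) {
    tl <- if (tails == "greater") "greater" else "two"
    th <- if (tails == "greater") "less" else "two"
    out$t_low <- paired_t_test(bounds$intermediate_score,
                               bounds$low_bound, tl)
    out$t_high <- paired_t_test(bounds$intermediate_score,
                                bounds$high_bound, th)
  } else {
    message("fewer than 2 subjects: paired tests skipped")
  }
  if (!is.null(traces) && length(traces) >= 2) {
    mat <- t(vapply(traces, function(tr) {
      bins <- cut(tr$times, n_bins, labels = FALSE)
      vapply(seq_len(n_bins), function(b) mean(tr$values[bins == b]),
             numeric(1))
    }, numeric(n_bins)))
    out$time_effect <- repeated_measures_anova(mat)
  }
  structure(out, class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> low %.3f < intermediate %.3f < high %.3f (n=%d)\n",
    x$low_bound, x$intermediate_score, x$high_bound, x$n_subjects))
  if (!is.null(x$t_low)) {
    cat(sprintf("  intermediate vs low:  t=%.2f p=%.2g\n", x$t_low$t,
                x$t_low$p))
    cat(sprintf("  intermediate vs high: t=%.2f p=%.2g\n", x$t_high$t,
                x$t_high$p))
  }
  if (!is.null(x$time_effect)) {
    cat(sprintf("  time effect: F=%.2f p=%.2g\n", x$time_effect$F,
                x$time_effect$p))
  }
  invisible(x)
}
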