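#' Per-trial biometric means
#'
#' Averages the biometric trace over each trial's temporal extent
#' (`[onset, onset + duration]`). At the 1 s trace stride a 2 s trial
#' averages at least two samples. Trials outside the trace span are
#' flagged missing and excluded downstream.
#'
#' @param trace a `biometric_trace`.
#' @param trials a `trial_table`.
#' @return Numeric vector, one value per trial (`NA` = outside span).
#' @export
trial_biometric_means <- function(trace, trials) {
  out <- rep(NA_real_, nrow(trials))
  t0 <- min(trace$times)
  t1 <- max(trace$times)
  for (i in seq_len(nrow(trials))) {
    a <- trials$onset[i]
    b <- trials$onset[i] + trials$duration[i]
    if (a < t0 - 1e-9 || b > t1 + 1e-9) next
    sel <- trace$times >= a & trace$times <= b
    if (any(sel)) out[i] <- mean(trace$values[sel])
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " trial(s) outside the trace span excluded")
  }
  out
}

#' Moving-average performance series
#'
#' Trailing moving averages of per-trial accuracy and reaction time over
#' trial order, for smoothing windows of 1 to 10 trials. The series has
#' length `n_trials - w + 1`; to pair with the biometric, average the
#' per-trial biometric means over the same trial spans (see
#' [permutation_test()], which does this internally).
#'
#' @param trials a `trial_table`.
#' @param w window length in trials, `1 <= w <= 10 <= n_trials`.
#' @return list with `acc`, `rt` (series), `w`.
#' @export
moving_average_performance <- function(trials, w) {
  n <- nrow(trials)
  if (w < 1 || w > 10) stop("moving-average window must be in 1..10 trials")
  if (w > n) stop("window longer than the number of trials")
  list(acc = trailing_moving_average(trials$correct, w),
       rt = trailing_moving_average(trials$rt, w),
       w = w)
}

# Trailing moving average of every column of a matrix (for the shuffled
# null: columns are permutations).
trailing_ma_matrix <- function(M, w) {
  n <- nrow(M)
  cs <- rbind(0, apply(M, 2, cumsum))
  (cs[(w + 1):(n + 1), , drop = FALSE] - cs[1:(n - w + 1), , drop = FALSE]) / w
}

#' Permutation test of a biometric-performance correlation
#'
#' Correlates the w-trial moving average of the per-trial biometric
#' means with the matching moving average of a performance metric, and
#' assesses significance against a permutation null: each of `n_iter`
#' iterations shuffles the raw per-trial performance across trials,
#' re-applies the same smoothing, and records the correlation with the
#' unshuffled biometric series. Shuffling before smoothing makes the
#' null respect the autocorrelation the moving average induces. The
#' two-sided p-value is `(1 + #\{|r_null| >= |r_obs|\}) / (n_iter + 1)`
#' (resolution 1/(n_iter+1); the +1 guards against p = 0).
#'
#' @param biometric per-trial biometric means (from
#'   [trial_biometric_means()]).
#' @param performance per-trial performance values (accuracy 0/1 or
#'   reaction times).
#' @param w moving-average window in trials.
#' @param n_iter number of permutations (default 3000).
#' @param seed RNG seed for the shuffles.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `permutation_result`: `w`, `r_observed`, `null` (length
#'   `n_iter`), `p`, `significant` (at 0.05), `degenerate`.
#' @export
permutation_test <- function(biometric, performance, w = 1, n_iter = 3000,
                             seed = 1, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(biometric) & !is.na(performance)
  biometric <- biometric[ok]
  performance <- performance[ok]
  n <- length(biometric)
  if (n < 20) stop("permutation test needs at least 20 trials")
  if (method == "spearman") {
    biometric <- rank(biometric)
    performance <- rank(performance)
  }
  bx <- trailing_moving_average(biometric, w)
  if (stats::sd(bx) == 0 || stats::sd(performance) == 0) {
    return(structure(
      list(w = w, r_observed = NA_real_, null = rep(NA_real_, n_iter),
           p = NA_real_, significant = FALSE, degenerate = TRUE),
      class = "permutation_result"))
  }
  py <- trailing_moving_average(performance, w)
  r_obs <- stats::cor(bx, py)
  P <- with_seed(seed, {
    matrix(performance[c(replicate(n_iter, sample.int(n)))], n, n_iter)
  })
  Pm <- trailing_ma_matrix(P, w)
  bxc <- bx - mean(bx)
  Pc <- sweep(Pm, 2, colMeans(Pm))
  denom <- sqrt(sum(bxc^2) * colSums(Pc^2))
  r_null <- as.vector(crossprod(bxc, Pc)) / denom
  r_null[!is.finite(r_null)] <- 0
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_iter + 1)
  structure(
    list(w = w, r_observed = r_obs, null = r_null, p = p,
         significant = is.finite(p) && p < 0.05, degenerate = FALSE),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> w=%d r=%.3f p=%.4g%s\n", x$w,
              x$r_observed, x$p,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Subject-level significance score over threat types
#'
#' The two threat types are assessed on separate days; a subject counts
#' as 1 when the biometric-performance correlation is significant for
#' both threat types, 0.5 for exactly one, and 0 for neither. A missing
#' threat type excludes the subject (returns `NA` with a message).
#'
#' @param results named list (or logical vector) with elements `person`
#'   and `object`: `permutation_result`s or plain logicals.
#' @return 0, 0.5, 1, or `NA` if a threat type is missing.
#' @export
subject_significance <- function(results) {
  get_sig <- function(x) {
    if (is.null(x)) return(NA)
    if (inherits(x, "permutation_result")) return(isTRUE(x$significant))
    isTRUE(as.logical(x))
  }
  s <- c(get_sig(results[["person"]]), get_sig(results[["object"]]))
  if (anyNA(s)) {
    message("missing threat type: subject excluded from the proportion")
    return(NA_real_)
  }
  sum(s) / 2
}
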