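#' Basic filtering, DC removal and average re-referencing
#'
#' Applies, in order: a 59-61 Hz zero-phase Butterworth band-stop (order
#' 4, forward-backward), a 0.1 Hz zero-phase Butterworth high-pass (order
#' 4), per-channel mean (DC offset) removal, and average re-referencing
#' of the EEG channels to the instantaneous mean of the retained EEG
#' channels (external ECG/EOG channels are filtered but excluded from the
#' reference).
#'
#' @param rec a `recording` with `fs > 122` Hz (the 61 Hz band-stop edge
#'   must lie below Nyquist).
#' @return The filtered `recording`.
#' @export
basic_filters <- function(rec) {
  if (rec$fs <= 122) stop("sampling rate too low: band-stop edge above Nyquist")
  nyq <- rec$fs / 2
  bs <- signal::butter(4, c(59, 61) / nyq, type = "stop")
  hp <- signal::butter(4, 0.1 / nyq, type = "high")
  dat <- rec$data
  for (j in seq_len(ncol(dat))) {
    x <- signal::filtfilt(bs, dat[, j])
    x <- signal::filtfilt(hp, x)
    dat[, j] <- x - mean(x)
  }
  retained <- retained_eeg(rec)
  eeg_idx <- which(rec$channel_names %in% retained)
  if (length(eeg_idx) >= 2) {
    ref <- rowMeans(dat[, eeg_idx, drop = FALSE])
    dat[, eeg_idx] <- dat[, eeg_idx] - ref
  }
  out <- rec
  out$data <- dat
  out
}

# EEG channels not flagged rejected.
retained_eeg <- function(rec) {
  eeg <- channels_by_role(rec, "EEG")
  setdiff(eeg, attr(rec, "rejected_channels"))
}

#' Flag outlier EEG channels by normalized spectral power
#'
#' Computes each EEG channel's total periodogram power in 1-250 Hz
#' (capped at Nyquist), normalizes by the across-channel median, takes
#' log10, and flags as rejected every channel exceeding mean + 3 SD of
#' that normalized measure. A single pass; flagged channels are kept in
#' the data (for later interpolation), not dropped.
#'
#' @param rec a `recording` with at least 4 EEG channels.
#' @return A list with `recording` (input with the `rejected_channels`
#'   attribute set) and `rejected` (character vector of labels).
#' @export
reject_channels <- function(rec) {
  eeg <- channels_by_role(rec, "EEG")
  if (length(eeg) < 4) stop("channel rejection needs at least 4 EEG channels")
  hi <- min(250, rec$fs / 2)
  pow <- vapply(eeg, function(ch) {
    band_power(rec$data[, ch], rec$fs, c(1, hi), taper = "rectangular")
  }, numeric(1))
  norm <- log10(pow / stats::median(pow))
  bad <- norm > mean(norm) + 3 * stats::sd(norm)
  rejected <- eeg[bad]
  if (length(rejected) == length(eeg)) {
    stop_mentalstate("all EEG channels rejected: pipeline failure",
                     "pipeline_failure")
  }
  out <- rec
  attr(out, "rejected_channels") <-
    union(attr(rec, "rejected_channels"), rejected)
  list(recording = out, rejected = rejected)
}

#' FastICA decomposition of the retained EEG channels
#'
#' Symmetric fixed-point ICA with the logcosh (tanh) contrast after PCA
#' whitening. The number of components equals the number of retained EEG
#' channels unless reduced. Deterministic for a fixed seed.
#'
#' @param rec a `recording` (only retained EEG channels are decomposed).
#' @param n_comp number of components (default: all retained channels).
#' @param seed RNG seed for the random orthogonal start.
#' @param maxit,tol fixed-point iteration controls.
#' @return An object of class `ic_decomposition`: `mixing`
#'   (channels x components), `sources` (samples x components), `means`,
#'   `channels`, plus empty `noise_rank`/`rejected` slots.
#' @export
ica_decompose <- function(rec, n_comp = NULL, seed = 1, maxit = 200,
                          tol = 1e-6) {
  chans <- retained_eeg(rec)
  X <- rec$data[, chans, drop = FALSE]
  n_comp <- n_comp %||% length(chans)
  stopifnot(n_comp >= 2, n_comp <= length(chans))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- stats::cov(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  # drop rank-deficient directions (average re-referencing removes one)
  rank <- sum(eg$values > max(eg$values) * 1e-9)
  n_comp <- min(n_comp, rank)
  keep <- seq_len(n_comp)
  # whitening matrix: components x channels
  K <- diag(1 / sqrt(eg$values[keep]), n_comp) %*% t(eg$vectors[, keep])
  Z <- Xc %*% t(K)
  W <- with_seed(seed, {
    W0 <- matrix(stats::rnorm(n_comp^2), n_comp)
    sym_decorrelate(W0)
  })
  n <- nrow(Z)
  for (it in seq_len(maxit)) {
    U <- Z %*% t(W)
    G <- tanh(U)
    gprime <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - diag(gprime, n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- Z %*% t(W)                      # samples x components
  unmix <- W %*% K                     # components x channels
  A <- t(Xc) %*% S %*% solve(crossprod(S))  # mixing: channels x components
  structure(
    list(mixing = A, sources = S, means = mu, channels = chans,
         noise_rank = NULL, rejected = integer(0)),
    class = "ic_decomposition"
  )
}

sym_decorrelate <- function(W) {
  s <- La.svd(W)
  s$u %*% s$vt
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf("<ic_decomposition> %d components over %d channels; %d rejected\n",
              ncol(x$sources), length(x$channels), length(x$rejected)))
  invisible(x)
}

# Reconstruct channel data from an IC decomposition, dropping `drop`.
ic_reconstruct <- function(ics, drop = integer(0)) {
  keep <- setdiff(seq_len(ncol(ics$sources)), drop)
  X <- ics$sources[, keep, drop = FALSE] %*% t(ics$mixing[, keep, drop = FALSE])
  X <- sweep(X, 2, ics$means, `+`)
  colnames(X) <- ics$channels
  X
}

#' Rank independent components by nuisance-signal correlation
#'
#' Orders components as artifact candidates by their maximum absolute
#' Pearson correlation with any nuisance channel (EOG, ECG,
#' accelerometer). Zero-variance components rank below every component
#' with a finite correlation.
#'
#' @param ics an `ic_decomposition`.
#' @param nuisance a `recording` whose ECG/EOG/AUX channels serve as
#'   nuisance signals, or a numeric matrix (samples x nuisance channels).
#' @return `ics` with `noise_rank` (component indices, most
#'   artifact-like first) and `rank_key` (the max |r| per component).
#' @export
rank_noise_components <- function(ics, nuisance) {
  N <- if (inherits(nuisance, "recording")) {
    idx <- which(nuisance$channel_roles %in% c("ECG", "EOG", "AUX"))
    if (!length(idx)) stop("no nuisance (ECG/EOG/AUX) channels available")
    nuisance$data[, idx, drop = FALSE]
  } else {
    as.matrix(nuisance)
  }
  if (!ncol(N)) stop("no nuisance channels available")
  n <- min(nrow(N), nrow(ics$sources))
  key <- vapply(seq_len(ncol(ics$sources)), function(j) {
    s <- ics$sources[seq_len(n), j]
    if (stats::sd(s) == 0) return(-Inf)
    max(abs(stats::cor(s, N[seq_len(n), , drop = FALSE])), na.rm = TRUE)
  }, numeric(1))
  ics$noise_rank <- order(key, decreasing = TRUE)
  ics$rank_key <- key
  ics
}

#' Iterative IC rejection under a signal-quality index
#'
#' Visits components in nuisance-rank order. Each candidate is added to
#' the rejected (noise) list and the quality index is evaluated on the
#' reconstruction without it; if the index changed by less than -0.001
#' relative to the reconstruction with it (a quality increase, since
#' lower is better for this index convention), the component stays
#' rejected, otherwise it is restored. The loop ends when every component
#' has been tried or when rejecting more would leave fewer than 25% of
#' components unrejected.
#'
#' @param ics an `ic_decomposition` with `noise_rank` populated.
#' @param rec the `recording` the decomposition came from (supplies
#'   sampling rate and channel metadata for the quality index).
#' @param quality_index function `recording -> score`, deterministic,
#'   lower = better quality; defaults to [default_quality_index()].
#' @param threshold change threshold (default -0.001).
#' @param floor minimum fraction of components that must stay unrejected.
#' @return `ics` with `rejected` set and a `qi_trace` data.frame
#'   (component, delta, kept) recording each decision.
#' @export
iterative_ic_rejection <- function(ics, rec,
                                   quality_index = default_quality_index,
                                   threshold = -0.001, floor = 0.25) {
  if (is.null(ics$noise_rank)) stop("noise_rank not populated; run rank_noise_components first")
  n_comp <- ncol(ics$sources)
  min_keep <- ceiling(floor * n_comp)
  qi_of <- function(drop) {
    sub <- rec
    sub$data <- ic_reconstruct(ics, drop)
    sub$channel_names <- ics$channels
    sub$channel_roles <- rep("EEG", length(ics$channels))
    score <- quality_index(sub)
    if (!is.finite(score)) {
      stop_mentalstate(
        paste0("quality index returned a non-finite score when removing components [",
               paste(drop, collapse = ","), "]"),
        "pipeline_failure")
    }
    score
  }
  rejected <- integer(0)
  trace <- list()
  for (comp in ics$noise_rank) {
    if (n_comp - length(rejected) - 1 < min_keep) break
    q_with <- qi_of(rejected)
    q_without <- qi_of(c(rejected, comp))
    delta <- q_without - q_with
    keep_rejected <- delta < threshold
    if (keep_rejected) rejected <- c(rejected, comp)
    trace[[length(trace) + 1]] <-
      data.frame(component = comp, delta = delta, rejected = keep_rejected)
  }
  ics$rejected <- sort(rejected)
  ics$qi_trace <- do.call(rbind, trace)
  ics
}

#' Default signal-quality index
#'
#' A proxy quality score: the fraction of total spectral power that is
#' non-physiological (59-61 Hz line band plus everything above 100 Hz),
#' averaged over channels. Lower is better, so removing an artifact
#' component decreases the score - matching the convention that a change
#' below -0.001 marks a quality increase.
#'
#' @param rec a `recording`.
#' @return A scalar score (lower = cleaner).
#' @export
default_quality_index <- function(rec) {
  nyq <- rec$fs / 2
  bad_of <- function(x) {
    tot <- band_power(x, rec$fs, c(0.5, nyq), taper = "rectangular")
    if (tot <= 0) return(0)
    bad <- band_power(x, rec$fs, c(59, min(61, nyq)), taper = "rectangular")
    if (nyq > 100) {
      bad <- bad + band_power(x, rec$fs, c(100, nyq), taper = "rectangular")
    }
    bad / tot
  }
  mean(apply(rec$data, 2, bad_of))
}

#' Back-project an IC decomposition into channel space
#'
#' Reconstructs the recording from the non-rejected components and writes
#' the result back into the corresponding channels.
#'
#' @param rec the `recording` the decomposition came from.
#' @param ics an `ic_decomposition` (after [iterative_ic_rejection()]).
#' @return The cleaned `recording`.
#' @export
ic_backproject <- function(rec, ics) {
  out <- rec
  out$data[, ics$channels] <- ic_reconstruct(ics, ics$rejected)
  out
}
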