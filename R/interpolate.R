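#' Interpolate rejected channels and remove slow drift
#'
#' Rejected EEG channels are rebuilt by spherical-spline interpolation
#' (order m = 4, 20 Legendre terms, regularization 1e-5) from the
#' retained EEG channels using the bundled montage positions; if fewer
#' than 3 positioned neighbors are available the function falls back to
#' inverse-distance weighting and says so. Afterwards every channel has
#' its centered moving average subtracted (window 1000 samples for
#' EEG/EOG, 50 samples for ECG; shrinking at the edges), which removes
#' drift and centers the signals at zero.
#'
#' @param rec a `recording`.
#' @param rejected labels to interpolate; defaults to the
#'   `rejected_channels` attribute.
#' @param montage electrode position table, see [eeg_montage()].
#' @return The interpolated, detrended `recording` (same shape and
#'   channel order; the rejected flag is cleared).
#' @export
interpolate_and_detrend <- function(rec, rejected = NULL,
                                    montage = eeg_montage()) {
  rejected <- rejected %||% attr(rec, "rejected_channels") %||% character(0)
  out <- rec
  eeg <- channels_by_role(rec, "EEG")
  good <- setdiff(eeg, rejected)
  bad <- intersect(rejected, eeg)
  if (length(bad)) {
    pos <- montage[match(c(good, bad), montage$label), c("x", "y", "z")]
    if (anyNA(pos)) {
      stop("montage positions missing for: ",
           paste(c(good, bad)[!stats::complete.cases(pos)], collapse = ", "))
    }
    P <- as.matrix(pos)
    Pg <- P[seq_along(good), , drop = FALSE]
    Pb <- P[length(good) + seq_along(bad), , drop = FALSE]
    if (length(good) < 3) {
      message("fewer than 3 retained neighbors: falling back to inverse-distance weighting")
      M <- idw_matrix(Pg, Pb)
    } else {
      M <- spherical_spline_matrix(Pg, Pb)
    }
    out$data[, bad] <- rec$data[, good, drop = FALSE] %*% t(M)
  }
  # moving-average drift correction
  for (j in seq_len(ncol(out$data))) {
    w <- if (rec$channel_roles[j] == "ECG") 50L else 1000L
    out$data[, j] <- out$data[, j] -
      centered_moving_average(out$data[, j], w)
  }
  attr(out, "rejected_channels") <- NULL
  attr(out, "interpolated_channels") <- bad
  out
}

# Legendre polynomials P_1..P_n evaluated at x (vector), by recurrence.
legendre_terms <- function(x, n_terms) {
  out <- matrix(0, length(x), n_terms)
  pm1 <- rep(1, length(x)) # P_0
  p <- x                   # P_1
  out[, 1] <- p
  for (n in 2:n_terms) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p
    p <- pn
  }
  out
}

# Spherical-spline kernel g(cos angle) (Perrin-style, order m).
ss_kernel <- function(cosang, m = 4, n_terms = 20) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_terms(pmin(pmax(cosang, -1), 1), n_terms)
  as.vector(P %*% coef) / (4 * pi)
}

# Interpolation operator: rows = bad electrodes, columns = good ones.
spherical_spline_matrix <- function(Pg, Pb, m = 4, n_terms = 20,
                                    lambda = 1e-5) {
  k <- nrow(Pg)
  G <- matrix(ss_kernel(as.vector(Pg %*% t(Pg)), m, n_terms), k, k)
  A <- rbind(cbind(G + diag(lambda, k), rep(1, k)),
             c(rep(1, k), 0))
  # solve for the linear operator mapping good-channel values to spline
  # coefficients, then evaluate at the bad positions
  rhs <- rbind(diag(k), rep(0, k))
  W <- solve(A, rhs) # (k+1) x k
  Gb <- matrix(ss_kernel(as.vector(Pb %*% t(Pg)), m, n_terms),
               nrow(Pb), k)
  cbind(Gb, rep(1, nrow(Pb))) %*% W
}

# Inverse-distance (great-circle) weighting fallback.
idw_matrix <- function(Pg, Pb) {
  M <- matrix(0, nrow(Pb), nrow(Pg))
  for (i in seq_len(nrow(Pb))) {
    d <- acos(pmin(pmax(Pg %*% Pb[i, ], -1), 1))
    w <- 1 / pmax(d, 1e-6)^2
    M[i, ] <- w / sum(w)
  }
  M
}

#' Full preprocessing pipeline
#'
#' Chains the cleaning stages: [basic_filters()], [reject_channels()],
#' ICA on the retained EEG channels, nuisance-correlation ranking,
#' [iterative_ic_rejection()] under the quality index, back-projection,
#' and [interpolate_and_detrend()]. A report of what was rejected is
#' attached as the `preprocess_report` attribute.
#'
#' @param rec a `recording`.
#' @param quality_index quality-index function (lower = better), see
#'   [default_quality_index()].
#' @param run_ica logical; skip the ICA stages when `FALSE` (e.g. for
#'   recordings with no nuisance channels).
#' @param seed seed for the ICA start.
#' @return The cleaned `recording`.
#' @export
preprocess <- function(rec, quality_index = default_quality_index,
                       run_ica = TRUE, seed = 1) {
  rec <- basic_filters(rec)
  rj <- reject_channels(rec)
  rec <- rj$recording
  report <- list(rejected_channels = rj$rejected, rejected_ics = integer(0))
  if (run_ica && length(retained_eeg(rec)) >= 2 &&
      any(rec$channel_roles %in% c("ECG", "EOG", "AUX"))) {
    ics <- ica_decompose(rec, seed = seed)
    ics <- rank_noise_components(ics, rec)
    ics <- iterative_ic_rejection(ics, rec, quality_index)
    rec <- ic_backproject(rec, ics)
    report$rejected_ics <- ics$rejected
    report$qi_trace <- ics$qi_trace
  }
  rec <- interpolate_and_detrend(rec, rj$rejected)
  attr(rec, "preprocess_report") <- report
  rec
}
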