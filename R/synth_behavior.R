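#' Synthesize novel-task trial behavior linked to latent states
#'
#' Generates a threat-detection trial table whose accuracy and reaction
#' time are driven by the latent states at trial time: correctness is
#' Bernoulli with success probability `sigmoid(b0 + b . L)` and reaction
#' time is `r0 + r . L` plus Gaussian noise, truncated to (0, 2] s (the
#' 2 s image presentation). In null mode the behavior links are zeroed so
#' trials are independent of the latents, which calibrates the
#' permutation test's type-I error.
#'
#' @param latents a [generate_latents()] trajectory covering the session.
#' @param profile a [subject_profile()] (supplies `behavior` links).
#' @param n_trials number of trials, >= 10.
#' @param null_mode logical; if `TRUE`, sets all latent links to zero.
#' @param trial_duration image presentation time in seconds.
#' @param iti inter-trial gap in seconds.
#' @param threat_type `"person"` or `"object"` (one type per session day).
#' @param n_blocks number of task blocks used to label trials.
#' @param seed optional seed; defaults to one derived from the profile.
#' @return A `trial_table` data.frame with columns `onset`, `duration`,
#'   `correct`, `rt`, `threat_type`, `block`.
#' @export
synthesize_behavior <- function(latents, profile = subject_profile(),
                                n_trials = 100, null_mode = FALSE,
                                trial_duration = 2, iti = 1,
                                threat_type = "person", n_blocks = 4,
                                seed = NULL) {
  stopifnot(n_trials >= 10)
  stride <- trial_duration + iti
  onsets <- 1 + (seq_len(n_trials) - 1) * stride
  if (max(onsets) + trial_duration > max(latents$times)) {
    stop("trials exceed the recording span: need ",
         max(onsets) + trial_duration, " s, have ", max(latents$times), " s")
  }
  bh <- profile$behavior
  b <- if (null_mode) bh$b * 0 else bh$b
  r <- if (null_mode) bh$r * 0 else bh$r
  mid <- onsets + trial_duration / 2
  L <- latent_drives(latents, mid)[, names(bh$b), drop = FALSE]
  seed <- seed %||% child_seed(profile$seed, paste0("behavior_", threat_type))
  out <- with_seed(seed, {
    p <- sigmoid(bh$b0 + as.vector(L %*% b))
    correct <- stats::rbinom(n_trials, 1, p)
    rt <- bh$r0 + as.vector(L %*% r) + stats::rnorm(n_trials, sd = bh$rt_sd)
    rt <- pmin(pmax(rt, 0.05), trial_duration)
    data.frame(
      onset = onsets, duration = trial_duration, correct = correct,
      rt = rt, threat_type = threat_type,
      block = paste0("block", ceiling(seq_len(n_trials) / (n_trials / n_blocks))),
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("trial_table", "data.frame")
  out
}
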