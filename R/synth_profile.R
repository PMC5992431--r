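#' Default effect-direction table for the synthetic EEG generator
#'
#' Signed multipliers linking latent states to band amplitudes per scalp
#' region. The default encodes the directions the committee models are
#' expected to pick up: fatigue raises frontal gamma and lowers
#' fronto-central alpha; stress raises theta over pre-frontal, central and
#' centro-parietal sites and frontal gamma, while lowering fronto-central
#' delta, frontal beta, and alpha over pre-frontal, fronto-central,
#' central and centro-parietal sites; mind-wandering (the complement of
#' attention) raises theta and delta and lowers alpha and beta scalp-wide.
#'
#' `latent` is one of `"fatigue"`, `"stress"`, `"mind_wandering"`;
#' `group` is a region from [channel_group()] or `"all"`. The amplitude
#' of the matching band carrier is scaled by `1 + effect * latent(t)`.
#'
#' @return data.frame with columns `latent`, `band`, `group`, `effect`.
#' @export
default_effect_table <- function() {
  rbind(
    data.frame(latent = "fatigue", band = "gamma", group = "frontal",
               effect = 0.5),
    data.frame(latent = "fatigue", band = "alpha", group = "fronto_central",
               effect = -0.3),
    data.frame(latent = "stress", band = "theta",
               group = c("pre_frontal", "central", "centro_parietal"),
               effect = 0.4),
    data.frame(latent = "stress", band = "gamma", group = "frontal",
               effect = 0.4),
    data.frame(latent = "stress", band = "delta", group = "fronto_central",
               effect = -0.3),
    data.frame(latent = "stress", band = "beta", group = "frontal",
               effect = -0.3),
    data.frame(latent = "stress", band = "alpha",
               group = c("pre_frontal", "fronto_central", "central",
                         "centro_parietal"),
               effect = -0.3),
    data.frame(latent = "mind_wandering", band = c("theta", "delta"),
               group = "all", effect = 0.4),
    data.frame(latent = "mind_wandering", band = c("alpha", "beta"),
               group = "all", effect = -0.3)
  )
}

#' Create a synthetic subject profile
#'
#' A profile fixes everything subject-specific about the generator:
#' per-channel, per-band baseline amplitudes; the effect-direction table;
#' cardiac parameters (mean RR interval, LF/HF modulation amplitudes and
#' their stress gains, beat-to-beat jitter); behavior-link coefficients;
#' and the RNG seed. The same seed and profile reproduce recordings
#' bit-for-bit.
#'
#' @param seed integer RNG seed for this subject.
#' @param channels EEG channel labels to simulate (default: the full
#'   29-label bundled montage).
#' @param effects effect-direction table, see [default_effect_table()].
#' @param band_scale named numeric, baseline carrier amplitude per band in
#'   signal units (microvolt-like).
#' @param noise_scale amplitude of the 1/f background.
#' @param rr_mean mean RR interval in seconds (must lie in \[0.5, 1.5\]).
#' @param lf_amp,hf_amp baseline RR modulation amplitudes (s) at 0.1 and
#'   0.3 Hz.
#' @param lf_gain,hf_gain unitless stress gains: the LF amplitude scales
#'   by `1 + lf_gain * stress`, the HF amplitude by `1 - hf_gain * stress`.
#' @param rr_jitter SD of beat-to-beat RR noise (s).
#' @param behavior list of behavior-link coefficients: `b0`, `b`
#'   (logit-scale intercept/slopes for correctness), `r0`, `r` (seconds,
#'   for reaction time), `rt_sd`.
#' @param subject subject identifier label.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(seed = 1L,
                            channels = eeg_montage()$label,
                            effects = default_effect_table(),
                            band_scale = c(delta = 12, theta = 8,
                                           alpha = 10, beta = 5,
                                           gamma = 3, high_gamma = 2),
                            noise_scale = 4,
                            rr_mean = 0.9,
                            lf_amp = 0.015, hf_amp = 0.04,
                            lf_gain = 1.5, hf_gain = 0.7,
                            rr_jitter = 0.003,
                            behavior = list(
                              b0 = 1.2,
                              b = c(fatigue = -1.2, stress = -0.8,
                                    mind_wandering = -1.0),
                              r0 = 0.6,
                              r = c(fatigue = 0.30, stress = 0.15,
                                    mind_wandering = 0.20),
                              rt_sd = 0.15
                            ),
                            subject = sprintf("S%03d", seed)) {
  stopifnot(rr_mean >= 0.5, rr_mean <= 1.5, all(band_scale > 0))
  bands <- eeg_band_table()$band
  stopifnot(all(bands %in% names(band_scale)))
  # per-channel baseline amplitude: band scale with mild seeded
  # channel-level heterogeneity
  baseline <- with_seed(child_seed(seed, "baseline"), {
    jit <- matrix(exp(stats::rnorm(length(bands) * length(channels),
                                   sd = 0.08)),
                  nrow = length(bands))
    sweep(jit, 1, band_scale[bands], `*`)
  })
  dimnames(baseline) <- list(bands, channels)
  structure(
    list(seed = seed, subject = subject, channels = channels,
         effects = effects, baseline = baseline,
         noise_scale = noise_scale,
         rr_mean = rr_mean, lf_amp = lf_amp, hf_amp = hf_amp,
         lf_gain = lf_gain, hf_gain = hf_gain, rr_jitter = rr_jitter,
         behavior = behavior),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s seed=%d, %d channels, RR %.2f s\n",
              x$subject, x$seed, length(x$channels), x$rr_mean))
  invisible(x)
}
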