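# Bundled 10-20 montage for the 29 scalp labels of a 32-channel cap in
# which three sites are repurposed as external channels (one ECG under the
# collarbone and two EOG). Positions are idealized spherical-head
# coordinates: each label is placed on the unit sphere from its standard
# flat-layout angle (degrees clockwise from the nose) and radius (0 =
# vertex, 1 = equator), which is accurate enough for spherical-spline
# interpolation and for defining scalp regions.

montage_layout <- function() {
  d <- rbind(
    c("Fp1", -18, 0.80), c("Fp2", 18, 0.80),
    c("F7", -54, 0.80), c("F3", -45, 0.57), c("Fz", 0, 0.40),
    c("F4", 45, 0.57), c("F8", 54, 0.80),
    c("FC5", -72, 0.62), c("FC1", -25, 0.28), c("FC2", 25, 0.28),
    c("FC6", 72, 0.62),
    c("T7", -90, 0.80), c("C3", -90, 0.40), c("Cz", 0, 0.00),
    c("C4", 90, 0.40), c("T8", 90, 0.80),
    c("CP5", -108, 0.62), c("CP1", -155, 0.28), c("CP2", 155, 0.28),
    c("CP6", 108, 0.62),
    c("P7", -126, 0.80), c("P3", -135, 0.57), c("Pz", 180, 0.40),
    c("P4", 135, 0.57), c("P8", 126, 0.80),
    c("PO4", 155, 0.72),
    c("O1", -162, 0.80), c("Oz", 180, 0.80), c("O2", 162, 0.80)
  )
  data.frame(
    label = d[, 1],
    angle = as.numeric(d[, 2]),
    radius = as.numeric(d[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Electrode montage with unit-sphere positions
#'
#' Returns the bundled scalp montage: the 29 EEG labels of the study cap
#' with idealized unit-sphere coordinates (x to the right, y to the front,
#' z up) and a scalp-region assignment used to express region-level
#' effect directions (e.g. "frontal gamma increases with fatigue").
#'
#' @return A data.frame with columns `label`, `x`, `y`, `z`, `group`.
#' @export
eeg_montage <- function() {
  lay <- montage_layout()
  inc <- lay$radius * pi / 2
  az <- lay$angle * pi / 180
  out <- data.frame(
    label = lay$label,
    x = sin(inc) * sin(az),
    y = sin(inc) * cos(az),
    z = cos(inc),
    stringsAsFactors = FALSE
  )
  out$group <- channel_group(out$label)
  out
}

#' Scalp region of an electrode label
#'
#' Maps 10-20 electrode labels to the scalp regions used by the synthetic
#' generator's effect-direction table: pre-frontal, frontal,
#' fronto-central, central, centro-parietal, temporal, parietal,
#' parieto-occipital, occipital.
#'
#' @param labels character vector of electrode labels.
#' @return character vector of region names (`NA` for unknown labels).
#' @export
channel_group <- function(labels) {
  groups <- list(
    pre_frontal = c("Fp1", "Fp2"),
    frontal = c("F7", "F3", "Fz", "F4", "F8"),
    fronto_central = c("FC5", "FC1", "FC2", "FC6"),
    central = c("C3", "Cz", "C4"),
    centro_parietal = c("CP5", "CP1", "CP2", "CP6"),
    temporal = c("T7", "T8"),
    parietal = c("P7", "P3", "Pz", "P4", "P8"),
    parieto_occipital = c("PO3", "PO4"),
    occipital = c("O1", "Oz", "O2")
  )
  map <- rep(names(groups), lengths(groups))
  names(map) <- unlist(groups)
  unname(map[labels])
}
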