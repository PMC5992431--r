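#' Generate latent mental-state trajectories for a calibration task
#'
#' Produces the ground-truth latent states that drive the synthetic
#' signals. Mental fatigue ramps linearly with time on task (to a cap that
#' grows with cognitive load); stress steps to a load-dependent constant
#' at task onset, strictly ordered breath-count < 1-back < 3-back;
#' attention is everywhere 1 except during mind-wandering bouts, which
#' occur only in the breath-count task and end with a button press
#' (`mw_events`). Bout structure is semi-Markov: attentive runs of mean
#' 60 s alternate with mind-wandering bouts of mean 20 s.
#'
#' @param task_kind `"breath_count"`, `"nback1"`, `"nback3"` or
#'   `"threat_detection"`.
#' @param duration task length in seconds (> 0).
#' @param profile a [subject_profile()].
#' @param dt latent sampling step in seconds.
#' @return An object of class `latent_traject`: list with `times`,
#'   `fatigue`, `stress`, `attention` (0/1 per sample), `mw_events`
#'   (button-press times) and `task`.
#' @export
generate_latents <- function(task_kind, duration, profile = subject_profile(),
                             dt = 0.1) {
  task_kind <- match.arg(task_kind, c("breath_count", "nback1", "nback3",
                                      "threat_detection"))
  stopifnot(duration > 0)
  times <- seq(0, duration, by = dt)
  levels <- latent_task_levels()[[task_kind]]
  fatigue <- levels$fatigue_cap * times / max(times)
  stress <- rep(levels$stress, length(times))
  attention <- rep(1L, length(times))
  mw_events <- numeric(0)

  if (task_kind == "breath_count") {
    bouts <- with_seed(child_seed(profile$seed, "mw_bouts"), {
      mw_bout_schedule(duration)
    })
    for (i in seq_len(nrow(bouts))) {
      attention[times >= bouts$start[i] & times < bouts$end[i]] <- 0L
    }
    mw_events <- bouts$end
  }

  structure(
    list(times = times, fatigue = fatigue, stress = stress,
         attention = attention, mw_events = mw_events, task = task_kind),
    class = "latent_traject"
  )
}

# Load-dependent latent levels per task. Stress ordering across the three
# calibration tasks is strict by construction; fatigue caps grow with
# load, so the second half of the high-load task carries high fatigue.
latent_task_levels <- function() {
  list(
    breath_count = list(stress = 0.10, fatigue_cap = 0.10),
    nback1 = list(stress = 0.50, fatigue_cap = 0.70),
    nback3 = list(stress = 0.90, fatigue_cap = 1.00),
    threat_detection = list(stress = 0.50, fatigue_cap = 0.80)
  )
}

# Alternating attentive runs / mind-wandering bouts. Runs are
# 20 + Exp(40) s, bouts 10 + Exp(10) s: the floors keep each bout long
# enough to contain the 8-to-2 s pre-press labeling window and give >= 3
# events in a 5-minute session in expectation.
mw_bout_schedule <- function(duration) {
  starts <- numeric(0)
  ends <- numeric(0)
  t <- 20 + stats::rexp(1, 1 / 40)
  while (t < duration) {
    bout <- 10 + stats::rexp(1, 1 / 10)
    if (t + bout >= duration) break
    starts <- c(starts, t)
    ends <- c(ends, t + bout)
    t <- t + bout + 20 + stats::rexp(1, 1 / 40)
  }
  data.frame(start = starts, end = ends)
}

#' @export
print.latent_traject <- function(x, ...) {
  cat(sprintf(
    "<latent_traject> %s, %.0f s: fatigue %.2f-%.2f, stress %.2f, %d mind-wandering events\n",
    x$task, max(x$times), min(x$fatigue), max(x$fatigue), x$stress[1],
    length(x$mw_events)
  ))
  invisible(x)
}

# Piecewise-linear interpolation of a latent channel onto arbitrary times.
latent_at <- function(latents, what, t) {
  y <- latents[[what]]
  if (what == "attention") {
    # binary: take nearest sample, no interpolation
    idx <- pmin(pmax(round(t / (latents$times[2] - latents$times[1])) + 1, 1),
                length(y))
    return(y[idx])
  }
  stats::approx(latents$times, y, xout = t, rule = 2)$y
}

# The three latent drive signals at given times, with attention expressed
# as mind-wandering (1 - attention) so that all drives are "more of the
# state" in the positive direction.
latent_drives <- function(latents, t) {
  cbind(
    fatigue = latent_at(latents, "fatigue", t),
    stress = latent_at(latents, "stress", t),
    mind_wandering = 1 - latent_at(latents, "attention", t)
  )
}
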