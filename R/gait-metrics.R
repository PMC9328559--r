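# Spatiotemporal and trunk centre-of-mass outcome measures per trial.
# All metrics are invariant to a constant mediolateral offset of the scene.

#' Step width mean and variability
#'
#' Each new placement is paired with the most recent contralateral placement;
#' step width is the absolute mediolateral distance between the two foot
#' reference points. Mean and SD are taken over the first `n_steps` steps
#' (when given), mirroring the study's 160-stride window.
#'
#' @param placements data.frame with columns `time`, `leg`, `ml`
#'   (see [extract_placements()] / [gt_placements()]).
#' @param n_steps optional number of steps to use (first n after the first
#'   pairable placement).
#' @return named vector `c(mean =, sd =, n =)`.
#' @export
step_width <- function(placements, n_steps = NULL) {
  p <- placements[order(placements$time), ]
  if (nrow(p) < 2) stop("need at least two placements")
  w <- numeric(0)
  last <- list(R = NA_real_, L = NA_real_)
  for (i in seq_len(nrow(p))) {
    other <- if (p$leg[i] == "R") "L" else "R"
    if (!is.na(last[[other]])) w <- c(w, abs(p$ml[i] - last[[other]]))
    last[[p$leg[i]]] <- p$ml[i]
  }
  if (!is.null(n_steps)) {
    if (length(w) < n_steps) stop("insufficient steps: need ", n_steps,
                                  ", have ", length(w))
    w <- w[seq_len(n_steps)]
  }
  c(mean = mean(w), sd = stats::sd(w), n = length(w))
}

beam_edges <- function(beam) {
  if (is.null(beam)) stop("beam geometry absent (normal-walking trial?)")
  c(lo = beam$center - beam$width / 2, hi = beam$center + beam$width / 2)
}

#' Foot placement error relative to the beam
#'
#' Per step, the distance by which the furthest-protruding foot edge overshoots
#' the nearer beam edge; zero when the whole foot is inside the beam. The
#' trial value is the mean over steps.
#'
#' @param placements data.frame with `ml_lo`, `ml_hi` foot-edge columns.
#' @param beam `list(center =, width =)` in meters.
#' @param n_steps optional number of steps to use.
#' @return named vector `c(mean =, n =)`.
#' @export
foot_placement_error <- function(placements, beam, n_steps = NULL) {
  be <- beam_edges(beam)
  p <- placements[order(placements$time), ]
  if (!is.null(n_steps)) p <- p[seq_len(min(n_steps, nrow(p))), ]
  err <- pmax(0, pmax(p$ml_hi - be["hi"], be["lo"] - p$ml_lo))
  c(mean = mean(err), n = nrow(p))
}

#' Percentage of steps placed wholly inside the beam
#'
#' A step counts as inside iff both the medial and lateral foot edges lie
#' within the beam.
#'
#' @inheritParams foot_placement_error
#' @return named vector `c(pct =, n =)`; `pct` in \[0, 100\].
#' @export
pct_steps_in_beam <- function(placements, beam, n_steps = NULL) {
  be <- beam_edges(beam)
  p <- placements[order(placements$time), ]
  if (!is.null(n_steps)) p <- p[seq_len(min(n_steps, nrow(p))), ]
  inside <- p$ml_lo >= be["lo"] & p$ml_hi <= be["hi"]
  c(pct = 100 * mean(inside), n = nrow(p))
}

#' Trunk centre-of-mass displacement and velocity metrics
#'
#' Per dominant-leg stride: displacement = peak-to-peak (max - min) of the
#' trunk ML position; velocity = mean absolute ML velocity (central
#' differences). Returns means and the displacement SD over strides.
#'
#' @param trunk_ml numeric vector of trunk ML position (m) at `fs` Hz, or a
#'   `gait_trial` (its trunk marker x column is used).
#' @param strides n x 2 matrix of stride start/end times, or a `gait_events`.
#' @param fs kinematic sampling rate.
#' @return named vector `c(disp_mean =, disp_sd =, vel_mean =, n =)`.
#' @export
trunk_com_metrics <- function(trunk_ml, strides, fs = NULL) {
  if (inherits(trunk_ml, "gait_trial")) {
    fs <- trunk_ml$fs_kin
    trunk_ml <- trunk_ml$markers$trunk[, 1]
  }
  if (inherits(strides, "gait_events")) strides <- strides$strides
  if (is.null(fs)) stop("fs required")
  t <- (seq_along(trunk_ml) - 1L) / fs
  vel <- com_velocity(trunk_ml, fs)
  disp <- vmean <- numeric(nrow(strides))
  for (i in seq_len(nrow(strides))) {
    sel <- t >= strides[i, 1] & t < strides[i, 2]
    disp[i] <- diff(range(trunk_ml[sel]))
    vmean[i] <- mean(abs(vel[sel]))
  }
  c(disp_mean = mean(disp), disp_sd = stats::sd(disp), vel_mean = mean(vmean),
    n = nrow(strides))
}

## Central-difference velocity (one-sided at the ends).
com_velocity <- function(x, fs) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  v
}

#' All gait metrics for one trial
#'
#' Convenience wrapper: extracts placements, limits them to the strides used,
#' and computes step width, beam scores (narrow condition), trunk CoM metrics
#' and support times.
#'
#' @param trial a `gait_trial`.
#' @param events a `gait_events` object for the trial.
#' @param n_strides number of strides the metrics are computed over.
#' @return named list of metric values.
#' @export
gait_metrics <- function(trial, events, n_strides = 160) {
  if (nrow(events$strides) < n_strides)
    stop("insufficient strides: need ", n_strides, ", have ", nrow(events$strides))
  strides <- events$strides[seq_len(n_strides), , drop = FALSE]
  pl <- extract_placements(events, trial)
  pl <- pl[pl$time <= strides[n_strides, 2] + 1e-9, ]
  sw <- step_width(pl)
  cm <- trunk_com_metrics(trial$markers$trunk[, 1], strides, trial$fs_kin)
  out <- list(step_width_mean = unname(sw["mean"]),
              step_width_sd = unname(sw["sd"]),
              com_disp_mean = unname(cm["disp_mean"]),
              com_disp_sd = unname(cm["disp_sd"]),
              com_vel_mean = unname(cm["vel_mean"]),
              n_strides = n_strides)
  if (trial$meta$condition == "narrow") {
    out$fpe_mean <- unname(foot_placement_error(pl, trial$beam)["mean"])
    out$pct_in_beam <- unname(pct_steps_in_beam(pl, trial$beam)["pct"])
  }
  sup <- support_times(events, trial, placements = pl)
  out$double_support_pct <- unname(sup$mean["double_pct"])
  out$single_support_dom_pct <- unname(sup$mean["single_dom_pct"])
  out
}
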