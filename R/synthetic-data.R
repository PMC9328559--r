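# Synthetic treadmill-gait generator with known ground truth.
#
# Emulates the study recordings: 11-channel surface EMG at 2000 Hz built from
# known synergy weightings and Gaussian-bump activation profiles amplitude-
# modulating band-limited carrier noise; 50 Hz marker trajectories with
# stride-to-stride variability and a tunable divergence gain; and a force-
# plate centre-of-pressure "butterfly" trace whose anterior extrema fall at
# known heel-strike times.

#' Default synergy muscle-weighting matrix
#'
#' A structured nonnegative 11 x k weighting matrix patterned on the synergy
#' organisation typically reported for treadmill walking: (1) dominant-leg
#' stance/push-off (soleus, lateral gastrocnemius, peroneus), (2) dominant-leg
#' weight acceptance (vastus lateralis, rectus femoris), (3) non-dominant-leg
#' stance (gluteus medius, rectus femoris), (4) pre-heel-strike of the
#' dominant leg (biceps femoris) and (5) its non-dominant mirror. Columns are
#' max-normalized to 1.
#'
#' @param k number of synergies (1..5 use the structured columns; k > 5 adds
#'   uniform low-level columns).
#' @return nonnegative 11 x k matrix with rownames set to the channel names.
#' @export
default_weightings <- function(k = 5) {
  stopifnot(is_count(k), k >= 1, k <= 11)
  m <- GAITSYN_MUSCLES
  W <- matrix(0.05, nrow = 11, ncol = max(k, 5), dimnames = list(m, NULL))
  W[c("SOD", "GLD", "PLD", "TAD"), 1] <- c(1.0, 0.9, 0.6, 0.15)
  W[c("VLD", "RFD", "GMD", "TAD"), 2] <- c(1.0, 0.8, 0.5, 0.3)
  W[c("GMN", "RFN", "BFN"), 3] <- c(1.0, 0.8, 0.2)
  W[c("BFD", "GMD", "TAD"), 4] <- c(1.0, 0.3, 0.4)
  W[c("BFN", "RFN"), 5] <- c(1.0, 0.35)
  W <- W[, seq_len(k), drop = FALSE]
  sweep(W, 2, apply(W, 2, max), "/")
}

#' Ground truth for one synthetic trial
#'
#' Draws the per-trial latent quantities every downstream estimate is scored
#' against: heel-strike times per leg (log-normal stride durations, default
#' CV 3 %), mediolateral foot placements and foot edges per step, synergy
#' weightings and activation-profile parameters, beam geometry, and the
#' divergence gain controlling stride-to-stride trunk dynamics.
#'
#' Coordinates: ML = x, AP = y, vertical = z, meters, treadmill frame fixed.
#' The dominant (right by default) leg's first heel strike is at t = 0 and
#' the trial spans whole dominant-leg strides.
#'
#' @param n_strides number of dominant-leg strides to generate beyond the
#'   lead-in (two spare strides are appended).
#' @param seed integer seed; the trial is bit-reproducible given the seed.
#' @param stride_mean,stride_cv mean (s) and coefficient of variation of the
#'   log-normal stride-duration distribution. 1.08 s corresponds to typical
#'   cadence at the study's fixed 3.5 km/h belt speed.
#' @param step_width_mean,step_width_sd target mean and SD (m) of the
#'   mediolateral distance between successive left/right placements.
#' @param foot_width foot width (m); edges are placed at center +/- width/2.
#' @param beam `list(center =, width =)` in meters for narrow-base trials
#'   (default width 0.12 when `condition = "narrow"`), or `NULL`.
#' @param condition `"normal"` or `"narrow"`; picks beam and step-width
#'   defaults when those are not given.
#' @param k,W number of synergies and 11 x k weighting matrix.
#' @param profile_centers,profile_widths,profile_amps per-synergy Gaussian
#'   bump center (% gait cycle), SD (% cycle) and amplitude.
#' @param divergence_gain unitless gain of the stochastic phase/amplitude
#'   perturbations of the trunk oscillator; 0 gives strictly periodic trunk
#'   motion in stride-normalized time.
#' @param ds_frac double-support duration as a fraction of a step; the CoP
#'   mediolateral transition is timed so its midline crossing occurs at this
#'   fraction after each heel strike.
#' @param phase_jitter SD of the left-leg phase offset around 0.5 stride.
#' @param lead_in seconds of extra gait prepended (to be trimmed downstream).
#' @return object of class `gait_ground_truth`.
#' @export
ground_truth <- function(n_strides = 160, seed = 1L,
                         stride_mean = 1.08, stride_cv = 0.03,
                         step_width_mean = NULL, step_width_sd = NULL,
                         foot_width = 0.10, beam = NULL,
                         condition = c("normal", "narrow"),
                         k = 5, W = default_weightings(k),
                         profile_centers = c(30, 5, 55, 90, 45)[seq_len(k)],
                         profile_widths = c(5, 4, 5, 4, 4)[seq_len(k)],
                         profile_amps = c(0.65, 0.75, 0.75, 0.95, 1)[seq_len(k)],
                         divergence_gain = 0.1, ds_frac = 0.2,
                         phase_jitter = 0.005, lead_in = 0,
                         dominant = "R") {
  condition <- match.arg(condition)
  stopifnot(is_count(n_strides), n_strides >= 1, stride_cv >= 0, ds_frac > 0,
            ds_frac < 0.5, foot_width > 0)
  if (ncol(W) != k || nrow(W) != 11)
    stop("W must be 11 x k with k = ", k, " columns")
  if (length(profile_centers) != k || length(profile_widths) != k ||
      length(profile_amps) != k)
    stop("profile parameter length must match k synergies")
  if (any(W < 0)) stop("W must be nonnegative")
  if (is.null(step_width_mean))
    step_width_mean <- if (condition == "narrow") 0.05 else 0.12
  if (is.null(step_width_sd))
    step_width_sd <- 0.02
  if (step_width_sd < 0) stop("step_width_sd must be >= 0")
  if (is.null(beam) && condition == "narrow")
    beam <- list(center = 0, width = 0.12)

  W <- sweep(W, 2, apply(W, 2, max), "/")  # columns max-normalized to 1
  rownames(W) <- GAITSYN_MUSCLES

  local_seed(seed, {
    n_extra <- ceiling(lead_in / stride_mean)
    n_tot <- n_strides + n_extra + 2L
    pad <- 0.3  # margin before the first / after the last heel strike
    sdlog <- sqrt(log(1 + stride_cv^2))
    durs <- stats::rlnorm(n_tot, meanlog = log(stride_mean) - sdlog^2 / 2,
                          sdlog = sdlog)
    hs_dom <- pad + c(0, cumsum(durs))           # n_tot + 1 dominant strikes
    phase <- 0.5 + stats::rnorm(n_tot, 0, phase_jitter)
    phase <- pmin(pmax(phase, 0.25), 0.75)
    hs_nd <- hs_dom[seq_len(n_tot)] + phase * durs

    ## interleaved step sequence: dom, nondom, ..., dom (terminal strike kept)
    ev_time <- c(as.vector(rbind(hs_dom[seq_len(n_tot)], hs_nd)),
                 hs_dom[n_tot + 1L])
    ev_leg <- c(rep(c(dominant, setdiff(c("L", "R"), dominant)), n_tot),
                dominant)

    mid <- if (!is.null(beam)) beam$center else 0
    eps <- if (step_width_sd > 0)
      stats::rnorm(length(ev_time), 0, step_width_sd / sqrt(2)) else
      numeric(length(ev_time))
    side_sign <- ifelse(ev_leg == "R", 1, -1)
    ml <- mid + side_sign * step_width_mean / 2 + eps
    edges <- cbind(ml - foot_width / 2, ml + foot_width / 2)

    structure(list(
      seed = seed, condition = condition, dominant = dominant,
      n_strides = n_strides, lead_in = lead_in,
      stride_mean = stride_mean, stride_cv = stride_cv,
      hs_dom = hs_dom, hs_nd = hs_nd,
      events = data.frame(time = ev_time, leg = ev_leg,
                          ml = ml, ml_lo = edges[, 1], ml_hi = edges[, 2]),
      step_width_mean = step_width_mean, step_width_sd = step_width_sd,
      foot_width = foot_width,
      beam = beam,
      beam_halfwidth = if (!is.null(beam)) beam$width / 2 else NA_real_,
      k = k, W_true = W,
      profile_params = data.frame(center = profile_centers,
                                  width = profile_widths,
                                  amplitude = profile_amps),
      divergence_gain = divergence_gain, ds_frac = ds_frac,
      duration = hs_dom[n_tot + 1L] + pad
    ), class = "gait_ground_truth")
  })
}

## Percentage of the dominant-leg gait cycle at arbitrary times.
cycle_pct <- function(t, hs_dom) {
  i <- findInterval(t, hs_dom)
  i <- pmin(pmax(i, 1L), length(hs_dom) - 1L)
  (t - hs_dom[i]) / (hs_dom[i + 1L] - hs_dom[i]) * 100
}

## True synergy activations (k x length(t)) evaluated at times t.
true_activations <- function(gt, t) {
  pct <- cycle_pct(t, gt$hs_dom)
  A <- matrix(0, gt$k, length(t))
  for (j in seq_len(gt$k)) {
    p <- gt$profile_params
    d <- circ_dist_pct(pct, p$center[j])
    A[j, ] <- p$amplitude[j] * exp(-d^2 / (2 * p$width[j]^2))
  }
  A
}

#' Generate raw synthetic EMG for a trial
#'
#' Each channel is the ground-truth envelope (synergy weightings times
#' Gaussian-bump activation profiles, plus a small tonic baseline) amplitude-
#' modulating zero-mean 20-450 Hz band-limited Gaussian carrier noise, with
#' additive white noise at the requested SNR and an optional mains sinusoid.
#'
#' @param gt a [ground_truth()] object.
#' @param fs sampling rate in Hz (study value 2000).
#' @param snr_db signal-to-noise ratio of the additive white noise in dB;
#'   `Inf` disables it.
#' @param line_hz optional mains interference frequency (e.g. 50), or `NULL`.
#' @param line_amp mains amplitude relative to the signal RMS.
#' @param tonic baseline activation added to every channel envelope.
#' @param amp_jitter_cv coefficient of variation of the log-normal per-stride,
#'   per-synergy activation amplitude jitter (between-stride variability).
#' @param muscle_noise amplitude of slow muscle-specific envelope activity not
#'   captured by the synergy model (sets the unexplained-variance floor of
#'   the factorization, as in real EMG).
#' @param seed RNG seed for carrier/noise (derived from `gt$seed` if `NULL`).
#' @return 11 x T matrix of class `numeric` with channel rownames; the true
#'   envelope is attached as attribute `"true_envelope"` and the true
#'   activations as `"true_activations"`.
#' @export
gen_emg <- function(gt, fs = 2000, snr_db = 20, line_hz = NULL,
                    line_amp = 0.5, tonic = 0.02, amp_jitter_cv = 0.15,
                    muscle_noise = 0.13, seed = NULL) {
  stopifnot(inherits(gt, "gait_ground_truth"), fs > 900)
  seed <- seed %||% (derive_seeds(gt$seed, 2L)[1L])
  t <- seq(0, gt$duration - 1 / fs, by = 1 / fs)
  A <- true_activations(gt, t)
  emg_env <- local_seed(seed, {
    if (amp_jitter_cv > 0) {
      ## between-stride variability of synergy recruitment strength
      ns <- length(gt$hs_dom) - 1L
      sdlog <- sqrt(log(1 + amp_jitter_cv^2))
      fj <- matrix(stats::rlnorm(ns * gt$k, -sdlog^2 / 2, sdlog), gt$k, ns)
      stride_of <- pmin(pmax(findInterval(t, gt$hs_dom), 1L), ns)
      A <- A * fj[, stride_of, drop = FALSE]
    }
    env <- gt$W_true %*% A + tonic
    if (muscle_noise > 0) {
      ## slow muscle-specific activity outside the synergy model; squared OU
      ## keeps the fluctuation large relative to the offset the factorization
      ## can absorb
      for (m in seq_len(11))
        env[m, ] <- env[m, ] + muscle_noise * ou_path(length(t), 1 / fs, 0.15)^2
    }
    rownames(env) <- GAITSYN_MUSCLES
    bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
    out <- matrix(0, 11, length(t), dimnames = list(GAITSYN_MUSCLES, NULL))
    for (m in seq_len(11)) {
      carrier <- zerophase(bp$b, bp$a, stats::rnorm(length(t)))
      carrier <- carrier / stats::sd(carrier)
      out[m, ] <- env[m, ] * carrier
    }
    if (is.finite(snr_db)) {
      sig_rms <- sqrt(mean(out^2))
      out <- out + stats::rnorm(length(out), 0, sig_rms / 10^(snr_db / 20))
    }
    list(emg = out, env = env, A = A)
  })
  emg <- emg_env$emg; env <- emg_env$env; A <- emg_env$A
  if (!is.null(line_hz)) {
    sig_rms <- sqrt(mean(emg^2))
    emg <- emg + matrix(rep(line_amp * sig_rms * sin(2 * pi * line_hz * t),
                            each = 11), nrow = 11)
  }
  attr(emg, "true_envelope") <- env
  attr(emg, "true_activations") <- A
  attr(emg, "fs") <- fs
  emg
}

## Ornstein-Uhlenbeck noise path, unit stationary variance.
ou_path <- function(n, dt, tau) {
  rho <- exp(-dt / tau)
  e <- stats::rnorm(n, 0, sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

#' Generate synthetic marker trajectories and centre-of-pressure trace
#'
#' The trunk mediolateral trajectory is a stochastic limit-cycle oscillator:
#' a harmonic function of gait phase whose phase and amplitude are perturbed
#' by Ornstein-Uhlenbeck noise scaled by `gt$divergence_gain`, plus white
#' measurement noise at the same gain. Foot reference and edge markers follow
#' the stored placements (constant in stance, smooth blend in swing, treadmill
#' belt motion in the AP axis). The CoP anterior-posterior component attains a
#' local maximum exactly at every stored heel-strike time and the mediolateral
#' component blends between stance feet, crossing their midline at
#' `ds_frac` of each step (the butterfly figure).
#'
#' @param gt a [ground_truth()] object.
#' @param fs kinematic sampling rate (study value 50 Hz).
#' @param fs_cop force-plate sampling rate.
#' @param trunk_amp trunk ML oscillation amplitude (m).
#' @param marker_noise RMS of white measurement noise on the trunk marker
#'   (m); fixed by the motion-capture system, independent of the divergence
#'   gain. Set to 0 for strictly periodic trajectories at gain 0.
#' @param cop_ap_amp anterior excursion of the CoP (m).
#' @param cop_noise_rms white noise RMS added to the CoP (m).
#' @param seed RNG seed (derived from `gt$seed` if `NULL`).
#' @return list with `markers` (named list of T x 3 matrices, columns x/y/z),
#'   `fs_kin`, `cop` (T x 2 matrix, columns x = ML, y = AP) and `fs_cop`.
#' @export
gen_kinematics <- function(gt, fs = 50, fs_cop = 1000,
                           trunk_amp = 0.02, marker_noise = 4e-4,
                           cop_ap_amp = 0.12, cop_noise_rms = 0, seed = NULL) {
  stopifnot(inherits(gt, "gait_ground_truth"))
  if (gt$n_strides < 1) stop("n_strides must be >= 1")
  seed <- seed %||% (derive_seeds(gt$seed, 2L)[2L])
  t <- seq(0, gt$duration - 1 / fs, by = 1 / fs)
  g <- gt$divergence_gain

  trunk_x <- local_seed(seed, {
    phi <- cycle_pct(t, gt$hs_dom) / 100
    x <- if (g > 0) {
      pert_p <- ou_path(length(t), 1 / fs, tau = 0.6)
      pert_a <- ou_path(length(t), 1 / fs, tau = 0.6)
      trunk_amp * (1 + 0.35 * g * pert_a) * sin(2 * pi * phi + 0.6 * g * pert_p)
    } else {
      trunk_amp * sin(2 * pi * phi)
    }
    if (marker_noise > 0) x <- x + stats::rnorm(length(t), 0, marker_noise)
    x
  })
  trunk <- cbind(x = trunk_x, y = 0, z = 1.1)

  markers <- c(list(trunk = trunk), foot_markers(gt, t))
  cop <- local_seed(seed + 1L, cop_trace(gt, fs_cop, cop_ap_amp, cop_noise_rms))
  list(markers = markers, fs_kin = fs, cop = cop$cop, fs_cop = fs_cop)
}

## Foot reference + edge marker trajectories for both feet at times t.
foot_markers <- function(gt, t, ap_amp = 0.25, stance_frac = 0.6) {
  out <- list()
  for (leg in c("R", "L")) {
    ev <- gt$events[gt$events$leg == leg, ]
    ## virtual strikes beyond both ends: early stance after the last strike,
    ## late swing before the first
    nr <- nrow(ev)
    step <- stats::median(diff(ev$time))
    ev <- rbind(ev[1, ], ev, ev[nr, ])
    ev$time[1] <- ev$time[2] - step
    ev$time[nr + 2L] <- ev$time[nr + 1L] + step
    hs <- ev$time
    i <- pmin(pmax(findInterval(t, hs), 1L), length(hs) - 1L)
    u <- (t - hs[i]) / (hs[i + 1L] - hs[i])   # own-cycle fraction, [0,1)
    u <- pmin(pmax(u, 0), 1)
    in_stance <- u < stance_frac
    sw <- pmax(u - stance_frac, 0) / (1 - stance_frac)  # swing fraction
    blend <- 0.5 * (1 - cos(pi * sw))
    ml <- ifelse(in_stance, ev$ml[i], ev$ml[i] + blend * (ev$ml[i + 1L] - ev$ml[i]))
    ap <- ifelse(in_stance, ap_amp - 2 * ap_amp * (u / stance_frac),
                 -ap_amp + 2 * ap_amp * blend)
    z <- ifelse(in_stance, 0.02, 0.02 + 0.05 * sin(pi * sw))
    side <- if (leg == "R") 1 else -1
    nm <- paste0("foot_", leg)
    out[[nm]] <- cbind(x = ml, y = ap, z = z)
    out[[paste0(nm, "_med")]] <- cbind(x = ml - side * gt$foot_width / 2,
                                       y = ap, z = z)
    out[[paste0(nm, "_lat")]] <- cbind(x = ml + side * gt$foot_width / 2,
                                       y = ap, z = z)
  }
  out
}

## CoP butterfly: AP cos^2 arches peaking at each heel strike; ML cosine
## blend from previous to current stance foot, crossing the midline at
## ds_frac of the step.
cop_trace <- function(gt, fs_cop, ap_amp, noise_rms) {
  t <- seq(0, gt$duration - 1 / fs_cop, by = 1 / fs_cop)
  ev <- gt$events[order(gt$events$time), ]
  ## virtual events beyond both ends so that every real heel strike is an
  ## interior anterior maximum of the AP trace
  nev <- nrow(ev)
  ev <- rbind(
    data.frame(time = 2 * ev$time[1] - ev$time[2], leg = ev$leg[2],
               ml = ev$ml[2], ml_lo = ev$ml_lo[2], ml_hi = ev$ml_hi[2]),
    ev,
    data.frame(time = 2 * ev$time[nev] - ev$time[nev - 1L], leg = ev$leg[nev - 1L],
               ml = ev$ml[nev - 1L], ml_lo = ev$ml_lo[nev - 1L],
               ml_hi = ev$ml_hi[nev - 1L]))
  et <- ev$time
  i <- pmin(pmax(findInterval(t, et), 1L), length(et) - 1L)
  tau <- (t - et[i]) / (et[i + 1L] - et[i])
  tau <- pmin(pmax(tau, 0), 1)
  ap <- ap_amp * cos(pi * tau)^2
  prev_ml <- c(ev$ml[1], ev$ml[-length(et)])
  bl <- pmin(tau / (2 * gt$ds_frac), 1)
  ml <- prev_ml[i] + (ev$ml[i] - prev_ml[i]) * 0.5 * (1 - cos(pi * bl))
  cop <- cbind(x = ml, y = ap)
  if (noise_rms > 0) cop <- cop + stats::rnorm(length(cop), 0, noise_rms)
  list(cop = cop, t = t)
}

#' Generate one complete synthetic trial
#'
#' Bundles [ground_truth()], [gen_emg()] and [gen_kinematics()] into a
#' `gait_trial` object carrying its ground truth.
#'
#' @param subject,time_point,condition,dominant_side trial metadata.
#' @param seed integer seed.
#' @param n_strides dominant-leg strides beyond the lead-in.
#' @param emg if `FALSE` the (expensive) EMG stream is skipped.
#' @param snr_db,line_hz passed to [gen_emg()].
#' @param fs_emg,fs_kin,fs_cop sampling rates.
#' @param ... further arguments to [ground_truth()].
#' @return object of class `gait_trial`.
#' @export
gen_trial <- function(subject = "S01", time_point = "Pre",
                      condition = c("normal", "narrow"),
                      seed = 1L, n_strides = 160, emg = TRUE,
                      snr_db = 20, line_hz = NULL,
                      fs_emg = 2000, fs_kin = 50, fs_cop = 1000,
                      dominant_side = "R", ...) {
  condition <- match.arg(condition)
  gt <- ground_truth(n_strides = n_strides, seed = seed,
                     condition = condition, dominant = dominant_side, ...)
  trial_from_gt(gt, subject, time_point, emg = emg, snr_db = snr_db,
                line_hz = line_hz, fs_emg = fs_emg, fs_kin = fs_kin,
                fs_cop = fs_cop)
}

trial_from_gt <- function(gt, subject, time_point, emg = TRUE, snr_db = 20,
                          line_hz = NULL, fs_emg = 2000, fs_kin = 50,
                          fs_cop = 1000) {
  kin <- gen_kinematics(gt, fs = fs_kin, fs_cop = fs_cop)
  e <- if (emg) gen_emg(gt, fs = fs_emg, snr_db = snr_db, line_hz = line_hz)
  structure(list(
    emg = e, fs_emg = if (emg) fs_emg else NA_real_,
    markers = kin$markers, fs_kin = kin$fs_kin,
    cop = kin$cop, fs_cop = kin$fs_cop,
    beam = gt$beam,
    meta = list(subject = subject, time_point = time_point,
                condition = gt$condition, dominant_side = gt$dominant),
    ground_truth = gt
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial>", x$meta$subject, x$meta$time_point, x$meta$condition,
      sprintf("| %d strides, %.1f s", x$ground_truth$n_strides,
              x$ground_truth$duration), "\n")
  invisible(x)
}

#' Ground-truth foot placements of a trial
#'
#' One row per step: heel-strike time, leg, foot-centre ML position and the
#' medial/lateral edge positions. This is the table every placement-based
#' metric is scored against, and the input contract of [step_width()].
#'
#' @param gt a [ground_truth()] object (or a `gait_trial`).
#' @return data.frame with columns `time`, `leg`, `ml`, `ml_lo`, `ml_hi`.
#' @export
gt_placements <- function(gt) {
  if (inherits(gt, "gait_trial")) gt <- gt$ground_truth
  stopifnot(inherits(gt, "gait_ground_truth"))
  gt$events
}

#' Generate a synthetic cohort manifest
#'
#' Lays out `n_subjects` x 3 time-points (Pre, Post1, Post2) x 2 conditions
#' (normal, narrow) and draws per-trial ground truth with subject-level
#' random variation plus any imposed effects. Heavy signal streams are not
#' materialized here; use [cohort_trial()] to generate a trial on demand.
#'
#' Imposed `effects` (all optional):
#' \describe{
#'   \item{step_width}{3 x 2 matrix (time-point x condition) of additive
#'     offsets (m) to mean step width.}
#'   \item{step_width_sd}{3 x 2 matrix of additive offsets (m) to its SD.}
#'   \item{fwhm_scale}{k x 2 matrix (synergy x condition) of multiplicative
#'     factors on the activation-bump widths.}
#'   \item{coa_shift}{k x 2 matrix of additive shifts (% cycle) on the
#'     activation-bump centers.}
#'   \item{divergence_gain}{3 x 2 matrix of additive offsets to the trunk
#'     divergence gain.}
#' }
#'
#' @param n_subjects number of subjects (>= 2 for cohort statistics; a
#'   single-subject manifest is allowed for plumbing).
#' @param effects named list as above; `NULL` or empty for a null cohort.
#' @param seed master seed; every trial seed is derived from it.
#' @param n_strides strides per trial.
#' @param k number of synergies.
#' @param base named list overriding baseline generator parameters
#'   (`step_width_normal`, `step_width_narrow`, `step_width_sd`,
#'   `divergence_gain`, `stride_mean`, `snr_db`, `lead_in`).
#' @param subject_sd named list of between-subject SDs
#'   (`step_width`, `trial_step_width`, `stride_mean`, `center`, `width`).
#' @return object of class `gait_cohort` with elements `manifest`
#'   (data.frame), `gts` (list of per-trial ground truths), `W_true`,
#'   `effects`, `seed`.
#' @export
gen_cohort <- function(n_subjects, effects = NULL, seed = 1L,
                       n_strides = 160, k = 5, base = list(),
                       subject_sd = list()) {
  stopifnot(is_count(n_subjects), n_subjects >= 1)
  b <- utils::modifyList(list(step_width_normal = 0.12, step_width_narrow = 0.05,
                              step_width_sd = 0.02, divergence_gain = 0.1,
                              stride_mean = 1.08, snr_db = 20, lead_in = 0),
                         base)
  ss <- utils::modifyList(list(step_width = 0.010, trial_step_width = 0.004,
                               stride_mean = 0.02, center = 1.0, width = 0.05),
                          subject_sd)
  eff <- effects %||% list()
  m32 <- function(x) {
    if (is.null(x)) return(matrix(0, 3, 2, dimnames = list(GAITSYN_TIMEPOINTS,
                                                           GAITSYN_CONDITIONS)))
    stopifnot(all(dim(x) == c(3, 2)))
    dimnames(x) <- list(GAITSYN_TIMEPOINTS, GAITSYN_CONDITIONS)
    x
  }
  mk2 <- function(x, fill) {
    if (is.null(x)) return(matrix(fill, k, 2, dimnames = list(NULL, GAITSYN_CONDITIONS)))
    stopifnot(all(dim(x) == c(k, 2)))
    dimnames(x) <- list(NULL, GAITSYN_CONDITIONS)
    x
  }
  eff_sw <- m32(eff$step_width); eff_swsd <- m32(eff$step_width_sd)
  eff_dg <- m32(eff$divergence_gain)
  eff_fw <- mk2(eff$fwhm_scale, 1); eff_coa <- mk2(eff$coa_shift, 0)

  W_true <- default_weightings(k)
  centers0 <- c(30, 5, 55, 90, 45)[seq_len(k)]
  widths0 <- c(5, 4, 5, 4, 4)[seq_len(k)]

  design <- expand.grid(condition = GAITSYN_CONDITIONS,
                        time_point = GAITSYN_TIMEPOINTS,
                        subject = sprintf("S%02d", seq_len(n_subjects)),
                        stringsAsFactors = FALSE)[, 3:1]
  n_tr <- nrow(design)
  seeds <- derive_seeds(seed, n_tr + n_subjects)
  trial_seeds <- seeds[seq_len(n_tr)]
  subj_seeds <- seeds[n_tr + seq_len(n_subjects)]

  gts <- vector("list", n_tr)
  manifest <- design
  manifest$seed <- trial_seeds
  manifest$step_width_mean <- NA_real_
  for (s in seq_len(n_subjects)) {
    sv <- local_seed(subj_seeds[s], list(
      sw = stats::rnorm(1, 0, ss$step_width),
      stride = stats::rnorm(1, 0, ss$stride_mean),
      centers = centers0 + stats::rnorm(k, 0, ss$center),
      widths = widths0 * exp(stats::rnorm(k, 0, ss$width)),
      trial_sw = stats::rnorm(6, 0, ss$trial_step_width)
    ))
    rows <- which(design$subject == sprintf("S%02d", s))
    for (jj in seq_along(rows)) {
      i <- rows[jj]
      tp <- design$time_point[i]; cond <- design$condition[i]
      swm <- (if (cond == "narrow") b$step_width_narrow else b$step_width_normal) +
        sv$sw + sv$trial_sw[jj] + eff_sw[tp, cond]
      swsd <- max(b$step_width_sd + eff_swsd[tp, cond], 0)
      gts[[i]] <- ground_truth(
        n_strides = n_strides, seed = trial_seeds[i],
        stride_mean = b$stride_mean + sv$stride,
        step_width_mean = max(swm, 0.005), step_width_sd = swsd,
        condition = cond, k = k, W = W_true,
        profile_centers = (sv$centers + eff_coa[, cond]) %% 100,
        profile_widths = sv$widths * eff_fw[, cond],
        divergence_gain = max(b$divergence_gain + eff_dg[tp, cond], 0),
        lead_in = b$lead_in)
      manifest$step_width_mean[i] <- swm
    }
  }
  structure(list(manifest = manifest, gts = gts, W_true = W_true,
                 effects = eff, seed = seed, base = b, k = k,
                 n_strides = n_strides),
            class = "gait_cohort")
}

#' Materialize one trial of a synthetic cohort
#'
#' @param cohort a [gen_cohort()] object.
#' @param i manifest row index.
#' @param emg whether to generate the EMG stream.
#' @param ... passed to [trial_from_gt()].
#' @return a `gait_trial`.
#' @export
cohort_trial <- function(cohort, i, emg = TRUE, ...) {
  stopifnot(inherits(cohort, "gait_cohort"), i >= 1, i <= nrow(cohort$manifest))
  trial_from_gt(cohort$gts[[i]], subject = cohort$manifest$subject[i],
                time_point = cohort$manifest$time_point[i], emg = emg,
                snr_db = cohort$base$snr_db, ...)
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat("<gait_cohort>", length(unique(x$manifest$subject)), "subjects x 3 time-points x 2 conditions,",
      x$n_strides, "strides/trial\n")
  invisible(x)
}

#' Lorenz-system time series (divergence-exponent oracle fixture)
#'
#' Integrates the Lorenz system (sigma = 10, rho = 28, beta = 8/3) with
#' `deSolve` and returns the x component after discarding a transient. The
#' largest Lyapunov exponent of this system (~0.906 nats/time) provides an
#' independent benchmark for the divergence-exponent estimator.
#'
#' @param n number of samples returned.
#' @param dt sampling interval (time units).
#' @param init initial state (perturbed canonical default).
#' @param transient time discarded before sampling.
#' @param sigma,rho,beta Lorenz parameters.
#' @return numeric vector of length `n` with attribute `"dt"`.
#' @export
lorenz_series <- function(n = 16000, dt = 0.02, init = c(1, 1, 20),
                          transient = 50, sigma = 10, rho = 28, beta = 8 / 3) {
  f <- function(t, y, p) {
    list(c(sigma * (y[2] - y[1]),
           y[1] * (rho - y[3]) - y[2],
           y[1] * y[2] - beta * y[3]))
  }
  times <- seq(0, transient + n * dt, by = dt)
  sol <- deSolve::ode(init, times, f, NULL, method = "ode45",
                      rtol = 1e-9, atol = 1e-9)
  x <- sol[, 2]
  x <- x[(length(x) - n + 1L):length(x)]
  attr(x, "dt") <- dt
  x
}
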