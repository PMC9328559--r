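# Gait events: heel-strike detection from the centre of pressure, leg
# assignment from foot kinematics, stride segmentation and support-phase
# durations.

#' Remove the initial habituation period of a trial
#'
#' Crops all streams (EMG, markers, CoP) consistently and re-anchors the time
#' base at zero; ground-truth event times, when present, are shifted and
#' truncated the same way.
#'
#' @param trial a `gait_trial`.
#' @param seconds duration to remove from the start (study value 30 s).
#' @return the cropped trial.
#' @export
trim_initial <- function(trial, seconds = 30) {
  stopifnot(inherits(trial, "gait_trial"))
  if (seconds <= 0) return(trial)
  dur <- nrow(trial$cop) / trial$fs_cop
  if (dur <= seconds) stop("trial shorter than the ", seconds, " s trim")
  crop_rows <- function(x, fs) {
    n0 <- floor(seconds * fs)
    x[(n0 + 1L):nrow(x), , drop = FALSE]
  }
  crop_cols <- function(x, fs) {
    n0 <- floor(seconds * fs)
    x[, (n0 + 1L):ncol(x), drop = FALSE]
  }
  if (!is.null(trial$emg)) {
    att <- attributes(trial$emg)
    trial$emg <- crop_cols(trial$emg, trial$fs_emg)
    if (!is.null(att$true_envelope))
      attr(trial$emg, "true_envelope") <- crop_cols(att$true_envelope, trial$fs_emg)
  }
  trial$markers <- lapply(trial$markers, crop_rows, fs = trial$fs_kin)
  trial$cop <- crop_rows(trial$cop, trial$fs_cop)
  gt <- trial$ground_truth
  if (!is.null(gt)) {
    shift <- function(v) { v <- v - seconds; v[v >= 0] }
    gt$hs_dom <- shift(gt$hs_dom)
    gt$hs_nd <- shift(gt$hs_nd)
    gt$events <- gt$events[gt$events$time >= seconds, , drop = FALSE]
    gt$events$time <- gt$events$time - seconds
    gt$duration <- gt$duration - seconds
    trial$ground_truth <- gt
  }
  trial
}

#' Detect heel-strike times from the centre of pressure
#'
#' Heel strikes are taken as the anterior extrema of the AP CoP component
#' (the tips of the butterfly figure): local maxima after mild low-pass
#' smoothing, with a refractory period between events.
#'
#' @param cop T x 2 matrix (columns x = ML, y = AP, meters) or a `gait_trial`.
#' @param fs CoP sampling rate (ignored when a trial is given).
#' @param min_sep minimum inter-event separation (s).
#' @param smooth_hz low-pass cutoff applied before peak picking (Hz).
#' @param min_height minimum peak height as a fraction of the AP range.
#' @return numeric vector of unlabeled event times (s).
#' @export
detect_heelstrikes <- function(cop, fs = NULL, min_sep = 0.4, smooth_hz = 10,
                               min_height = 0.3) {
  if (inherits(cop, "gait_trial")) { fs <- cop$fs_cop; cop <- cop$cop }
  if (is.null(fs)) stop("fs required")
  ap <- cop[, 2]
  rng <- diff(range(ap))
  if (rng < 1e-9) stop("no events found: constant CoP")
  bw <- signal::butter(2, smooth_hz / (fs / 2), type = "low")
  aps <- zerophase(bw$b, bw$a, ap)
  pk <- pracma::findpeaks(aps, minpeakdistance = max(round(min_sep * fs), 1L),
                          minpeakheight = min(aps) + min_height * diff(range(aps)))
  if (is.null(pk) || nrow(pk) == 0) stop("no events found")
  idx <- sort(pk[, 2])
  (idx - 1L) / fs
}

#' Assign detected events to legs and segment strides
#'
#' Each event is assigned to the foot whose reference marker is more anterior
#' at the event time (the landing foot is at its anterior extreme at heel
#' strike). Alternation is then enforced: of consecutive same-leg events the
#' later one is dropped and logged; more than `max_violations` of dropped
#' events is treated as a detection failure.
#'
#' @param events numeric vector of event times from [detect_heelstrikes()].
#' @param markers named list with `foot_R` and `foot_L` T x 3 trajectories
#'   (or a `gait_trial`).
#' @param fs_kin kinematic sampling rate.
#' @param dominant dominant side, `"R"` or `"L"`; strides are dominant
#'   heel-strike to next dominant heel-strike.
#' @param max_violations error threshold on the fraction of dropped events.
#' @return object of class `gait_events`: list with `events` (data.frame
#'   time/leg), `heelstrikes` (per-leg lists), `strides` (n x 2 matrix of
#'   start/end times), `dominant`, `fs_kin` and a `log` of repairs.
#' @export
assign_legs <- function(events, markers, fs_kin = NULL, dominant = "R",
                        max_violations = 0.1) {
  if (inherits(markers, "gait_trial")) {
    fs_kin <- markers$fs_kin
    dominant <- markers$meta$dominant_side %||% dominant
    markers <- markers$markers
  }
  if (is.null(fs_kin)) stop("fs_kin required")
  stopifnot(all(c("foot_R", "foot_L") %in% names(markers)))
  tkin <- (seq_len(nrow(markers$foot_R)) - 1L) / fs_kin
  ap_r <- stats::approx(tkin, markers$foot_R[, 2], xout = events, rule = 2)$y
  ap_l <- stats::approx(tkin, markers$foot_L[, 2], xout = events, rule = 2)$y
  leg <- ifelse(ap_r >= ap_l, "R", "L")

  keep <- rep(TRUE, length(events))
  log <- character()
  last <- ""
  for (i in seq_along(events)) {
    if (leg[i] == last) {
      keep[i] <- FALSE
      log <- c(log, sprintf("dropped same-leg event at %.3f s (%s)", events[i], leg[i]))
    } else last <- leg[i]
  }
  if (sum(!keep) > max_violations * length(events))
    stop("leg alternation violated for ", sum(!keep), " of ", length(events),
         " events; heel-strike detection likely failed")
  ev <- data.frame(time = events[keep], leg = leg[keep])

  hs_dom <- ev$time[ev$leg == dominant]
  if (length(hs_dom) < 2) stop("fewer than two dominant-leg heel-strikes")
  strides <- cbind(start = hs_dom[-length(hs_dom)], end = hs_dom[-1])
  ## keep only strides containing exactly one contralateral heel strike
  contra <- ev$time[ev$leg != dominant]
  ncontra <- vapply(seq_len(nrow(strides)), function(i)
    sum(contra > strides[i, 1] & contra < strides[i, 2]), integer(1))
  bad <- which(ncontra != 1L)
  if (length(bad)) {
    log <- c(log, sprintf("dropped stride %d (%d contralateral events)",
                          bad, ncontra[bad]))
    strides <- strides[ncontra == 1L, , drop = FALSE]
  }
  structure(list(events = ev,
                 heelstrikes = split(ev$time, ev$leg),
                 strides = strides, dominant = dominant,
                 fs_kin = fs_kin, log = log),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>", nrow(x$events), "events,", nrow(x$strides),
      "dominant-leg strides", if (length(x$log)) sprintf("(%d repairs)", length(x$log)), "\n")
  invisible(x)
}

#' Foot placements at heel strike
#'
#' Reads the landing foot's reference and edge marker positions at each event
#' time. During stance the markers are stationary, so the value at the event
#' is the placement.
#'
#' @param events a `gait_events` object.
#' @param markers named marker list (or a `gait_trial`).
#' @param fs_kin kinematic sampling rate.
#' @return data.frame with `time`, `leg`, `ml` (foot reference ML), `ml_lo`,
#'   `ml_hi` (leftmost/rightmost foot-edge ML).
#' @export
extract_placements <- function(events, markers, fs_kin = NULL) {
  if (inherits(markers, "gait_trial")) {
    fs_kin <- markers$fs_kin
    markers <- markers$markers
  }
  stopifnot(inherits(events, "gait_events"))
  tkin <- (seq_len(nrow(markers$foot_R)) - 1L) / fs_kin
  get_ml <- function(name, at)
    stats::approx(tkin, markers[[name]][, 1], xout = at, rule = 2)$y
  ev <- events$events
  ml <- ml_lo <- ml_hi <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    nm <- paste0("foot_", ev$leg[i])
    e1 <- get_ml(paste0(nm, "_med"), ev$time[i])
    e2 <- get_ml(paste0(nm, "_lat"), ev$time[i])
    ml[i] <- get_ml(nm, ev$time[i])
    ml_lo[i] <- min(e1, e2); ml_hi[i] <- max(e1, e2)
  }
  data.frame(time = ev$time, leg = ev$leg, ml = ml, ml_lo = ml_lo, ml_hi = ml_hi)
}

#' Single- and double-support durations as percentages of the stride
#'
#' Toe-off is not observable from heel-strike events alone; it is
#' approximated from the CoP mediolateral transition: the double support
#' after each heel strike is taken to end when the CoP crosses the midline
#' between the previous and the new stance foot. Per dominant-leg stride the
#' two double-support phases and the two single-support phases are expressed
#' as percentages of the stride time (they sum to 100 by construction).
#'
#' @param events a `gait_events` object.
#' @param cop T x 2 CoP matrix (or a `gait_trial`).
#' @param fs_cop CoP sampling rate.
#' @param placements placement table from [extract_placements()] (computed
#'   from the trial when omitted and a trial is given).
#' @return list with `per_stride` (data.frame: stride, double_pct,
#'   single_dom_pct, single_nd_pct) and `mean` (named vector of the three
#'   trial means).
#' @export
support_times <- function(events, cop, fs_cop = NULL, placements = NULL) {
  if (inherits(cop, "gait_trial")) {
    if (is.null(placements)) placements <- extract_placements(events, cop)
    fs_cop <- cop$fs_cop
    cop <- cop$cop
  }
  stopifnot(inherits(events, "gait_events"), !is.null(placements))
  tc <- (seq_len(nrow(cop)) - 1L) / fs_cop
  ev <- placements[order(placements$time), ]
  n <- nrow(ev)
  ds <- rep(NA_real_, n - 1L)  # double-support duration of step i
  for (i in 2:n) {
    m_prev <- ev$ml[i - 1L]; m_cur <- ev$ml[i]
    if (abs(m_cur - m_prev) < 1e-9) next
    mid <- (m_cur + m_prev) / 2
    bound <- if (i < n) ev$time[i + 1L] else Inf
    sel <- which(tc > ev$time[i] & tc < bound)
    if (!length(sel)) next
    s <- sign(m_cur - mid)
    rel <- s * (cop[sel, 1] - mid)
    j <- which(rel >= 0)[1]
    if (is.na(j)) next
    if (j == 1L) { ds[i - 1L] <- tc[sel[1]] - ev$time[i]; next }
    ## linear interpolation of the crossing instant
    i2 <- sel[j]; i1 <- sel[j - 1L]
    f <- (0 - s * (cop[i1, 1] - mid)) / (s * (cop[i2, 1] - mid) - s * (cop[i1, 1] - mid))
    ds[i - 1L] <- tc[i1] + f * (tc[i2] - tc[i1]) - ev$time[i]
  }
  ## map steps onto dominant strides
  st <- events$strides
  res <- data.frame(stride = seq_len(nrow(st)), double_pct = NA_real_,
                    single_dom_pct = NA_real_, single_nd_pct = NA_real_)
  for (k in seq_len(nrow(st))) {
    i0 <- which(abs(ev$time - st[k, 1]) < 1e-9)[1]
    if (is.na(i0) || i0 + 2L > n) next
    stride_t <- st[k, 2] - st[k, 1]
    d1 <- ds[i0]        # after dominant heel strike (contralateral leg trailing)
    d2 <- ds[i0 + 1L]   # after contralateral heel strike
    if (is.na(d1) || is.na(d2)) next
    step1 <- ev$time[i0 + 1L] - ev$time[i0]
    step2 <- ev$time[i0 + 2L] - ev$time[i0 + 1L]
    res$double_pct[k] <- (d1 + d2) / stride_t * 100
    res$single_dom_pct[k] <- (step1 - d1) / stride_t * 100
    res$single_nd_pct[k] <- (step2 - d2) / stride_t * 100
  }
  ok <- stats::complete.cases(res)
  list(per_stride = res,
       mean = c(double_pct = mean(res$double_pct[ok]),
                single_dom_pct = mean(res$single_dom_pct[ok]),
                single_nd_pct = mean(res$single_nd_pct[ok])))
}
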