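# EMG preprocessing: raw multi-channel EMG -> normalized envelopes ->
# stride-time-normalized activation matrix E (muscles x strides*100).
#
# All filters are Butterworth and applied zero-phase (forward-backward), so
# the chain commutes with time reversal and adds no group delay that would
# bias activation-timing metrics.

as_emg_matrix <- function(emg) {
  if (is.null(dim(emg))) emg <- matrix(emg, nrow = 1)
  emg
}

#' High-pass filter EMG
#'
#' Zero-phase Butterworth high-pass, applied per channel. The 50 Hz default
#' removes movement artefact and, deliberately aggressive, the low-frequency
#' content that would otherwise leak into envelopes.
#'
#' @param emg channels x samples matrix (a vector is treated as one channel).
#' @param fs sampling rate (Hz); must exceed twice the cutoff.
#' @param cutoff high-pass cutoff (Hz).
#' @param order filter order (applied twice by the forward-backward pass).
#' @return filtered matrix of the same shape.
#' @export
emg_highpass <- function(emg, fs, cutoff = 50, order = 4) {
  if (fs <= 2 * cutoff) stop("sampling rate too low for a ", cutoff, " Hz high-pass")
  emg <- as_emg_matrix(emg)
  bw <- signal::butter(order, cutoff / (fs / 2), type = "high")
  out <- t(apply(emg, 1, function(x) zerophase(bw$b, bw$a, x)))
  dimnames(out) <- dimnames(emg)
  out
}

#' Notch-filter mains interference and its harmonics
#'
#' Cascaded zero-phase Butterworth band-stop filters at `base`, `2*base`, ...
#' up to (below) the Nyquist frequency, each `bw` Hz wide.
#'
#' @inheritParams emg_highpass
#' @param base mains frequency (Hz).
#' @param bw stop-band width (Hz).
#' @param order per-notch Butterworth order.
#' @return filtered matrix of the same shape.
#' @export
emg_notch_harmonics <- function(emg, fs, base = 50, bw = 1, order = 1) {
  if (base >= fs / 2) stop("notch base frequency must be below Nyquist")
  emg <- as_emg_matrix(emg)
  freqs <- base * seq_len(floor((fs / 2 - bw / 2 - 1e-9) / base))
  freqs <- freqs[freqs - bw / 2 > 0]
  filts <- lapply(freqs, function(f0)
    signal::butter(order, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2), type = "stop"))
  bs <- lapply(filts, function(f) as.numeric(f$b))
  as_ <- lapply(filts, function(f) as.numeric(f$a))
  npad <- min(ncol(emg) - 1L, 4000L)
  out <- t(apply(emg, 1, function(x) zerophase_cascade(bs, as_, x, npad)))
  dimnames(out) <- dimnames(emg)
  out
}

#' EMG envelope via the analytic signal
#'
#' Rectifies the Hilbert analytic signal -- its magnitude
#' sqrt(x^2 + H(x)^2), with H a windowed FIR Hilbert transformer -- and
#' low-pass filters the result zero-phase. The output is nonnegative up to
#' filter ringing, which is clipped at zero.
#'
#' @inheritParams emg_highpass
#' @param lp low-pass cutoff (Hz).
#' @param order low-pass Butterworth order.
#' @return nonnegative envelope matrix of the same shape.
#' @export
emg_envelope <- function(emg, fs, lp = 20, order = 2) {
  emg <- as_emg_matrix(emg)
  bw <- signal::butter(order, lp / (fs / 2), type = "low")
  out <- t(apply(emg, 1, function(x) {
    e <- sqrt(x^2 + hilbert_fir(x)^2)
    pmax(zerophase(bw$b, bw$a, e), 0)
  }))
  dimnames(out) <- dimnames(emg)
  out
}

#' Normalize envelopes to the per-trial maximum
#'
#' Each channel is divided by its own maximum within the trial ("per
#' measurement point per trial"), so the normalized maximum is exactly 1 and
#' trials of the same subject are normalized independently.
#'
#' @param envelope nonnegative channels x samples matrix.
#' @return matrix with per-channel maxima equal to 1.
#' @export
emg_normalize <- function(envelope) {
  envelope <- as_emg_matrix(envelope)
  if (any(envelope < 0)) stop("envelope must be nonnegative")
  mx <- apply(envelope, 1, max)
  bad <- which(mx == 0)
  if (length(bad))
    stop("all-zero envelope channel(s): ",
         paste(rownames(envelope)[bad] %||% bad, collapse = ", "))
  envelope / mx
}

#' Stride-time normalization of envelopes (the E matrix)
#'
#' Cuts the envelope into dominant-leg strides (heel-strike to next ipsilateral
#' heel-strike, half-open) and linearly resamples each onto a uniform grid of
#' `samples` points, keeping the first `n_strides` strides. Columns are
#' ordered stride-major: stride 1 samples 1..100, stride 2 samples 1..100, ...
#'
#' @param envelope channels x samples matrix at rate `fs`.
#' @param events a [gait_events()] object (or list with element `strides`, a
#'   two-column matrix of stride start/end times in seconds).
#' @param fs envelope sampling rate (Hz).
#' @param samples samples per normalized stride.
#' @param n_strides strides to keep (study value 160).
#' @return object of class `stride_emg`: list with `E` (channels x
#'   n_strides*samples), `stride_index` (column -> stride map), `samples`,
#'   `n_strides`, `muscles`.
#' @export
emg_time_normalize <- function(envelope, events, fs, samples = 100L,
                               n_strides = 160L) {
  envelope <- as_emg_matrix(envelope)
  strides <- if (is.matrix(events)) events else events$strides
  if (is.null(strides)) stop("events must contain a stride table")
  if (nrow(strides) < n_strides)
    stop("insufficient strides: need ", n_strides, ", have ", nrow(strides))
  if (any(strides[, 2] <= strides[, 1]) ||
      (nrow(strides) > 1 && any(diff(strides[, 1]) <= 0)))
    stop("stride boundaries must be strictly increasing")
  strides <- strides[seq_len(n_strides), , drop = FALSE]
  tmax <- (ncol(envelope) - 1L) / fs
  if (strides[n_strides, 2] > tmax + 1 / fs)
    stop("stride boundaries exceed envelope duration")
  t <- (seq_len(ncol(envelope)) - 1L) / fs
  grid <- as.vector(vapply(seq_len(n_strides), function(s)
    strides[s, 1] + (seq_len(samples) - 1L) / samples *
      (strides[s, 2] - strides[s, 1]), numeric(samples)))
  E <- matrix(NA_real_, nrow(envelope), n_strides * samples,
              dimnames = list(rownames(envelope), NULL))
  for (m in seq_len(nrow(envelope)))
    E[m, ] <- stats::approx(t, envelope[m, ], xout = grid, rule = 2)$y
  structure(list(E = E, stride_index = rep(seq_len(n_strides), each = samples),
                 samples = as.integer(samples), n_strides = as.integer(n_strides),
                 muscles = rownames(envelope)),
            class = "stride_emg")
}

#' Full EMG preprocessing chain
#'
#' High-pass, notch cascade, analytic-signal envelope, per-trial maximum
#' normalization and stride-time normalization in one call.
#'
#' @param emg channels x samples raw EMG.
#' @param fs sampling rate (Hz).
#' @param events gait events for stride segmentation.
#' @param config list of chain parameters (see [default_config()]):
#'   `hp_cutoff`, `hp_order`, `notch_base`, `notch_bw`, `notch_order`,
#'   `lp_cutoff`, `lp_order`, `samples_per_stride`, `n_strides`.
#' @return a `stride_emg` object (see [emg_time_normalize()]).
#' @export
preprocess_emg <- function(emg, fs, events, config = default_config()) {
  x <- emg_highpass(emg, fs, config$hp_cutoff, config$hp_order)
  x <- emg_notch_harmonics(x, fs, config$notch_base, config$notch_bw,
                           config$notch_order)
  x <- emg_envelope(x, fs, config$lp_cutoff, config$lp_order)
  x <- emg_normalize(x)
  emg_time_normalize(x, events, fs, config$samples_per_stride, config$n_strides)
}
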