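# Local divergence exponent (LDE) of trunk CoM velocity via Rosenstein's
# algorithm: time-normalized series -> delay embedding -> nearest-neighbour
# log-divergence curve -> linear fit over half a stride.

#' Stride-time normalization of a 1-D series
#'
#' Resamples each stride onto `per_stride` samples by linear interpolation
#' and concatenates them (amplitudes untouched, between-stride variability
#' preserved). 160 strides yield the study's 16000-sample series.
#'
#' @param x numeric series sampled at `fs` Hz.
#' @param strides n x 2 matrix of stride start/end times (s), or a
#'   `gait_events` object.
#' @param fs sampling rate (Hz).
#' @param per_stride samples per normalized stride.
#' @param n_strides strides to use (defaults to all provided).
#' @return numeric vector of length `n_strides * per_stride`.
#' @export
normalize_series <- function(x, strides, fs, per_stride = 100L,
                             n_strides = NULL) {
  if (inherits(strides, "gait_events")) strides <- strides$strides
  n_strides <- n_strides %||% nrow(strides)
  if (nrow(strides) < n_strides)
    stop("insufficient strides: need ", n_strides, ", have ", nrow(strides))
  strides <- strides[seq_len(n_strides), , drop = FALSE]
  t <- (seq_along(x) - 1L) / fs
  out <- numeric(n_strides * per_stride)
  for (s in seq_len(n_strides))
    out[(s - 1L) * per_stride + seq_len(per_stride)] <-
      resample_stride(t, x, strides[s, 1], strides[s, 2], per_stride)
  out
}

#' Delay embedding
#'
#' Reconstructs state vectors x(t) = \[s(t), s(t + delay), ...,
#' s(t + (dim-1) delay)\]; with the study parameters (dim 5, delay 10) a
#' series of length N yields N - 40 states.
#'
#' @param series numeric vector.
#' @param dim embedding dimension.
#' @param delay delay in samples.
#' @return (N - (dim-1)*delay) x dim state matrix.
#' @export
delay_embed <- function(series, dim = 5L, delay = 10L) {
  n <- length(series)
  span <- (dim - 1L) * delay
  if (n <= span) stop("series too short for the requested embedding")
  nrows <- n - span
  sapply(seq_len(dim), function(j) series[(j - 1L) * delay + seq_len(nrows)])
}

#' Mean log-divergence curve of nearest state-space neighbours
#'
#' For every state the nearest Euclidean neighbour with temporal separation
#' greater than `exclusion_window` is found; the log of the pair distance is
#' then tracked over increasing offsets, averaging across pairs per offset.
#' Pairs running off the series end drop out of later offsets; offsets with
#' fewer than `min_pairs_frac` of the initial pairs are truncated.
#'
#' @param states state matrix from [delay_embed()].
#' @param exclusion_window Theiler-style temporal exclusion (samples);
#'   default half a stride at 100 samples/stride.
#' @param horizon number of offsets to track (samples).
#' @param min_pairs_frac minimum surviving-pair fraction before truncation.
#' @return object of class `divergence_curve`: data.frame with `offset`
#'   (samples, starting at 0), `log_divergence`, `n_pairs`.
#' @export
divergence_curve <- function(states, exclusion_window = 50L, horizon = 100L,
                             min_pairs_frac = 0.5) {
  stopifnot(is.matrix(states), nrow(states) >= 2)
  res <- .divergence_curve_cpp(states, as.integer(exclusion_window),
                               as.integer(horizon))
  first_bad <- which(res$n_pairs < min_pairs_frac * res$n_pairs[1])[1]
  last <- if (is.na(first_bad)) length(res$curve) else max(first_bad - 1L, 1L)
  out <- data.frame(offset = 0:(last - 1L),
                    log_divergence = res$curve[seq_len(last)],
                    n_pairs = res$n_pairs[seq_len(last)])
  class(out) <- c("divergence_curve", "data.frame")
  out
}

#' Fit the local divergence exponent
#'
#' Least-squares slope of the mean log-divergence curve over offsets
#' \[0, window), expressed per stride (slope per sample times samples per
#' stride).
#'
#' @param curve a [divergence_curve()] result (or numeric vector of log
#'   divergences at offsets 0, 1, ...).
#' @param window fit window in samples (study choice: half a stride, 50).
#' @param per_stride samples per stride used to scale the slope.
#' @return named vector `c(lde =, slope =)`: `lde` in ln-units per stride,
#'   `slope` per sample.
#' @export
fit_lde <- function(curve, window = 50L, per_stride = 100L) {
  y <- if (is.data.frame(curve)) curve$log_divergence else as.numeric(curve)
  if (length(y) < window) stop("divergence curve shorter than the fit window")
  y <- y[seq_len(window)]
  x <- seq_len(window) - 1L
  b <- stats::coef(stats::lm(y ~ x))[["x"]]
  c(lde = b * per_stride, slope = b)
}

#' Local divergence exponent of a trial's trunk CoM velocity
#'
#' Full Rosenstein pipeline: trunk ML velocity, stride-time normalization
#' (100 samples/stride), delay embedding (dim 5, delay 10), nearest-neighbour
#' log-divergence curve and linear fit over half a stride.
#'
#' @param trial a `gait_trial` (or numeric trunk ML series with `fs` given).
#' @param events `gait_events` (or stride matrix).
#' @param n_strides strides to use.
#' @param fs kinematic sampling rate when `trial` is a numeric series.
#' @param dim,delay embedding parameters.
#' @param exclusion_window,horizon,fit_window divergence-curve parameters
#'   (samples).
#' @return object of class `stability_result`: list with `lde` (ln/stride),
#'   `slope`, `curve`, `series`, `embedding`.
#' @export
stability_lde <- function(trial, events, n_strides = 160, fs = NULL,
                          dim = 5L, delay = 10L, exclusion_window = 50L,
                          horizon = 100L, fit_window = 50L) {
  x <- if (inherits(trial, "gait_trial")) {
    fs <- trial$fs_kin
    trial$markers$trunk[, 1]
  } else trial
  if (is.null(fs)) stop("fs required")
  vel <- com_velocity(x, fs)
  series <- normalize_series(vel, events, fs, per_stride = 100L,
                             n_strides = n_strides)
  states <- delay_embed(series, dim = dim, delay = delay)
  curve <- divergence_curve(states, exclusion_window = exclusion_window,
                            horizon = horizon)
  fit <- fit_lde(curve, window = fit_window, per_stride = 100L)
  structure(list(lde = unname(fit["lde"]), slope = unname(fit["slope"]),
                 curve = curve, series = series,
                 embedding = c(dim = dim, delay = delay)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> LDE = %.4f ln/stride (dim %d, delay %d, %d offsets)\n",
              x$lde, x$embedding["dim"], x$embedding["delay"], nrow(x$curve)))
  invisible(x)
}
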