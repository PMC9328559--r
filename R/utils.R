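# Internal numerical utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generator calls
#' do not perturb the global random stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Zero-phase IIR filtering with odd-reflection padding
#'
#' Applies the filter forward and backward (squared magnitude response, zero
#' phase). Ends are padded with the odd reflection of the signal so that the
#' operation commutes with time reversal and startup transients decay inside
#' the padding, which matters for the high-Q notch filters (ring time of a
#' 1 Hz-wide stop band at 2000 Hz is several hundred samples).
#' @noRd
zerophase <- function(b, a, x, npad = NULL) {
  n <- length(x)
  npad <- npad %||% min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 1000L))
  if (n < 4L) stop("signal too short to filter")
  .cascade_filtfilt(list(as.numeric(b)), list(as.numeric(a)), as.numeric(x),
                    as.integer(npad))
}

## Zero-phase filtering through a cascade of filters sharing one padding.
zerophase_cascade <- function(bs, as_, x, npad) {
  .cascade_filtfilt(bs, as_, as.numeric(x), as.integer(npad))
}

#' Discrete Hilbert transform via an antisymmetric FIR transformer
#'
#' Windowed (Blackman) type-III FIR Hilbert transformer applied with odd-
#' reflection padding. The kernel is antisymmetric, so the transform exactly
#' anticommutes with time reversal and the analytic magnitude
#' sqrt(x^2 + H(x)^2) commutes with it. Accurate above ~ fs * 2/half;
#' envelopes here are computed on signals already high-passed at 50 Hz.
#' @noRd
hilbert_fir <- function(x, half = 200L) {
  k <- seq(-half, half)
  h <- numeric(length(k))
  odd <- k %% 2L != 0L
  h[odd] <- 2 / (pi * k[odd])
  w <- 0.42 + 0.5 * cos(pi * k / half) + 0.08 * cos(2 * pi * k / half)
  .fir_conv_sym(as.numeric(x), h * w)
}

## Linear-interpolation resampling of one stride onto a uniform grid of
## `samples` points covering [t0, t1) (endpoint excluded, half-open stride).
resample_stride <- function(t, x, t0, t1, samples = 100L) {
  grid <- t0 + (seq_len(samples) - 1L) / samples * (t1 - t0)
  stats::approx(t, x, xout = grid, rule = 2)$y
}

## Wrap angles into [0, 2*pi).
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}

## Circular distance on a 0..period ring (used for % gait-cycle arithmetic).
circ_dist_pct <- function(x, center, period = 100) {
  d <- (x - center) %% period
  pmin(d, period - d)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

## rbind data.frames with non-identical columns, filling with NA.
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[, cols, drop = FALSE]
  }))
}
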