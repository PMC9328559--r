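# Shared fixtures, generated once per test run and memoized (several are
# expensive: full preprocessing chains, Lorenz integration).

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

## 40-stride EMG-bearing trial at the study's SNR, with detected events and
## the preprocessed stride-normalized activation matrix.
fx_trial40 <- function() memo("trial40", gen_trial(seed = 5, n_strides = 40))

fx_events40 <- function() memo("events40", {
  tr <- fx_trial40()
  assign_legs(detect_heelstrikes(tr), tr)
})

fx_E40 <- function() memo("E40", {
  tr <- fx_trial40()
  preprocess_emg(tr$emg, tr$fs_emg, fx_events40(),
                 default_config(n_strides = 40L, trim_s = 0))
})

## Kinematics-only trial for event/metric tests.
fx_kin20 <- function() memo("kin20", gen_trial(seed = 42, n_strides = 20, emg = FALSE))

## Lorenz x-series sampled for the divergence-exponent benchmark.
fx_lorenz <- function() memo("lorenz", lorenz_series(n = 16000, dt = 0.04))

## Noise-free periodic series whose period (~100 samples) matches the
## embedding geometry (delay 10, dim 5 -> lag phases uniform mod pi).
fx_periodic <- function() {
  i <- 0:7999
  T <- 100.01
  sin(2 * pi * i / T) + 0.5 * sin(4 * pi * i / T + 1) + 0.3 * sin(6 * pi * i / T + 2)
}

## Match events to ground truth and compute detection F1 at a tolerance.
event_f1 <- function(detected, truth, tol = 0.020) {
  tp <- sum(vapply(truth, function(t0) min(abs(detected - t0)) <= tol, TRUE))
  fp <- sum(vapply(detected, function(t0) min(abs(truth - t0)) > tol, TRUE))
  prec <- tp / (tp + fp)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
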