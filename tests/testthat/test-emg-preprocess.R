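# Filter chain: frequency responses, envelope fidelity, normalization and
# stride-time normalization of the E matrix.

fs <- 2000
tvec <- (0:39999) / fs
interior <- 5000:35000
rms <- function(v) sqrt(mean(v[interior]^2))

test_that("high-pass removes DC and low frequencies, passes the EMG band", {
  dc <- emg_highpass(rep(1, 10000), fs)
  expect_lt(max(abs(dc)), 1e-6)
  s10 <- sin(2 * pi * 10 * tvec)
  expect_lt(20 * log10(rms(as.numeric(emg_highpass(s10, fs))) / rms(s10)), -40)
  s200 <- sin(2 * pi * 200 * tvec)
  expect_equal(rms(as.numeric(emg_highpass(s200, fs))) / rms(s200), 1,
               tolerance = 0.01)
  expect_error(emg_highpass(s10, fs = 80), "too low")
})

test_that("the notch cascade suppresses mains harmonics with narrow stops", {
  s50 <- sin(2 * pi * 50 * tvec)
  expect_lt(rms(as.numeric(emg_notch_harmonics(s50, fs))) / rms(s50), 0.05)
  s150 <- sin(2 * pi * 150 * tvec)
  expect_lt(rms(as.numeric(emg_notch_harmonics(s150, fs))) / rms(s150), 0.05)

  ## broadband loss agrees with the spectral integral of the designed
  ## cascade response (|H|^4: two passes), computed independently here
  withr::with_seed(3, {
    w <- rnorm(2e5)
    loss <- 1 - mean(as.numeric(emg_notch_harmonics(w, fs))^2) / mean(w^2)
  })
  f <- seq(0, fs / 2, by = 0.05)
  H2 <- rep(1, length(f))
  for (f0 in 50 * (1:19)) {
    bw <- signal::butter(1, c(f0 - 0.5, f0 + 0.5) / (fs / 2), type = "stop")
    z <- exp(-1i * pi * f / (fs / 2))
    resp <- (bw$b[1] + bw$b[2] * z + bw$b[3] * z^2) /
      (bw$a[1] + bw$a[2] * z + bw$a[3] * z^2)
    H2 <- H2 * Mod(resp)^2
  }
  theo <- mean(1 - H2^2)
  expect_equal(loss, theo, tolerance = 0.15)
  expect_lt(loss, 0.05)
})

test_that("the envelope recovers slow amplitude modulation", {
  withr::with_seed(4, {
    carrier <- as.numeric(emg_highpass(rnorm(length(tvec)), fs, cutoff = 20))
    a <- 1 + 0.9 * sin(2 * pi * 1.5 * tvec)
    env <- as.numeric(emg_envelope(a * carrier, fs))
  })
  expect_gt(cor(env[interior], a[interior]), 0.98)
  ## zero in, zero out; constant-amplitude tone -> near-constant envelope
  expect_equal(max(abs(emg_envelope(rep(0, 5000), fs))), 0)
  tone <- sin(2 * pi * 100 * tvec)
  e <- as.numeric(emg_envelope(tone, fs))
  expect_lt(sd(e[interior]) / mean(e[interior]), 0.02)
})

test_that("normalization scales each channel to a per-trial maximum of 1", {
  x <- rbind(a = c(0.5, 3.2, 1), b = c(0.1, 0.2, 0.4))
  n1 <- emg_normalize(x)
  expect_equal(unname(apply(n1, 1, max)), c(1, 1))
  expect_equal(unname(n1["a", 2]), 1)
  ## idempotent
  expect_equal(emg_normalize(n1), n1)
  ## all-zero channel names the offender
  bad <- rbind(a = c(1, 2), dead = c(0, 0))
  expect_error(emg_normalize(bad), "dead")
  expect_error(emg_normalize(rbind(a = c(-1, 1))), "nonnegative")
})

test_that("stride-time normalization yields samples x strides columns", {
  ## 160 strides of 1 s at 100 Hz -> E with 16000 columns
  env <- matrix(rep(1 + sin(2 * pi * (0:16199) / 100), 2), nrow = 2,
                byrow = TRUE)
  strides <- cbind(0:159, 1:160)
  E <- emg_time_normalize(env, strides, fs = 100, n_strides = 160L)
  expect_equal(ncol(E$E), 16000L)
  expect_equal(E$stride_index[c(1, 101, 16000)], c(1L, 2L, 160L))
  ## constant envelope stays constant
  Ec <- emg_time_normalize(matrix(2, 1, 16200), strides, fs = 100,
                           n_strides = 160L)
  expect_equal(unname(Ec$E[1, ]), rep(2, 16000))
  ## insufficient strides reports the count
  expect_error(emg_time_normalize(env, strides[1:30, ], fs = 100,
                                  n_strides = 160L), "30")
  ## misordered boundaries are rejected
  bad <- strides; bad[2, ] <- c(5, 4)
  expect_error(emg_time_normalize(env, bad, fs = 100, n_strides = 160L),
               "increasing")
})

test_that("the whole chain is zero-phase: it commutes with time reversal", {
  withr::with_seed(2, x <- rnorm(5000))
  chain <- function(v)
    as.numeric(emg_envelope(emg_notch_harmonics(emg_highpass(v, fs), fs), fs))
  a <- chain(x)
  b <- chain(rev(x))
  expect_lt(max(abs(rev(b) - a)) / max(abs(a)), 1e-9)
})

test_that("the chain recovers per-stride activation shape at SNR 20 dB", {
  tr <- fx_trial40()
  E <- fx_E40()
  ## mean stride profile per muscle vs the noiseless profile implied by the
  ## generator (weightings x Gaussian bumps + tonic)
  pct <- seq(0, 99) + 0.5
  gt <- tr$ground_truth
  A <- sapply(seq_len(gt$k), function(j) {
    d <- pmin((pct - gt$profile_params$center[j]) %% 100,
              (gt$profile_params$center[j] - pct) %% 100)
    gt$profile_params$amplitude[j] * exp(-d^2 / (2 * gt$profile_params$width[j]^2))
  })
  truth <- gt$W_true %*% t(A)
  prof <- sapply(seq_len(11), function(m)
    rowMeans(matrix(E$E[m, ], nrow = 100)))
  cors <- vapply(seq_len(11), function(m) cor(prof[, m], truth[m, ]), 0)
  expect_gt(mean(cors), 0.95)
})
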