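# The generator is the study's stand-in data source: its ground truth must
# satisfy the protocol invariants and be bit-reproducible.

test_that("trials are bit-reproducible from their seed", {
  a <- gen_trial(seed = 9, n_strides = 4)
  b <- gen_trial(seed = 9, n_strides = 4)
  expect_identical(a$emg, b$emg)
  expect_identical(a$markers, b$markers)
  expect_identical(a$cop, b$cop)
  d <- gen_trial(seed = 10, n_strides = 4)
  expect_false(identical(a$emg, d$emg))
})

test_that("ground truth satisfies the protocol invariants", {
  gt <- ground_truth(n_strides = 12, seed = 3, condition = "narrow")
  expect_true(all(gt$W_true >= 0))
  expect_equal(unname(apply(gt$W_true, 2, max)), rep(1, 5))
  ## 12 cm projected beam -> 0.06 m half-width
  expect_equal(gt$beam_halfwidth, 0.06)
  ## per-leg heel-strike times strictly increasing, legs alternate globally
  ev <- gt$events
  for (leg in c("R", "L"))
    expect_true(all(diff(ev$time[ev$leg == leg]) > 0))
  expect_true(all(ev$leg[-1] != ev$leg[-nrow(ev)]))
  ## foot edges bracket the reference point by half the foot width
  expect_equal(ev$ml_hi - ev$ml_lo, rep(gt$foot_width, nrow(ev)))
})

test_that("zero step-width variability yields constant realized widths", {
  gt <- ground_truth(n_strides = 10, seed = 2, step_width_mean = 0.11,
                     step_width_sd = 0)
  sw <- step_width(gt_placements(gt))
  expect_equal(unname(sw["mean"]), 0.11)
  expect_equal(unname(sw["sd"]), 0)
})

test_that("zero divergence gain gives stride-periodic trunk motion", {
  ## stride length commensurate with the 50 Hz grid so strides are
  ## sample-aligned
  gt <- ground_truth(n_strides = 10, seed = 4, stride_mean = 1.0,
                     stride_cv = 0, phase_jitter = 0, divergence_gain = 0)
  kin <- gen_kinematics(gt, marker_noise = 0)
  strides <- cbind(gt$hs_dom[1:10], gt$hs_dom[2:11])
  s <- normalize_series(kin$markers$trunk[, 1], strides, kin$fs_kin)
  m <- matrix(s, nrow = 100)
  expect_lt(max(abs(m - m[, 1])), 1e-9)
})

test_that("mains interference appears only when requested", {
  gt <- ground_truth(n_strides = 3, seed = 6)
  power_at <- function(emg, f0, fs = 2000) {
    x <- emg[1, ]
    n <- 2048
    i <- seq_len(n)
    ## Goertzel-style single-bin power, avoids FFT length issues
    mean(abs(sum(x[i] * exp(-2i * pi * f0 * (i - 1) / fs)))^2) / n^2
  }
  clean <- gen_emg(gt, line_hz = NULL)
  mains <- gen_emg(gt, line_hz = 50)
  expect_gt(power_at(mains, 50) / power_at(clean, 50), 10)
})

test_that("noise-free EMG envelopes track the stored true envelope", {
  gt <- ground_truth(n_strides = 20, seed = 8)
  emg <- gen_emg(gt, snr_db = Inf, line_hz = NULL, muscle_noise = 0,
                 amp_jitter_cv = 0)
  env <- emg_envelope(emg_notch_harmonics(emg_highpass(emg, 2000), 2000), 2000)
  truth <- attr(emg, "true_envelope")
  interior <- 2000:(ncol(emg) - 2000)
  ## single-realization limit: the 20 Hz low-pass leaves a Rayleigh residual
  ## of the stochastic carrier (~10 % CV), so per-sample correlation tops
  ## out below 1 even without additive noise
  cors <- vapply(seq_len(11), function(m)
    cor(env[m, interior], truth[m, interior]), 0)
  expect_true(all(cors > 0.95))
  ## averaging across strides removes the carrier residual
  tr <- gaitsyn:::trial_from_gt(gt, "S", "Pre", emg = FALSE)
  ev <- assign_legs(detect_heelstrikes(tr), tr)
  En <- emg_time_normalize(env, ev, fs = 2000, n_strides = 20L)
  Tn <- emg_time_normalize(truth, ev, fs = 2000, n_strides = 20L)
  prof_cors <- vapply(seq_len(11), function(m)
    cor(rowMeans(matrix(En$E[m, ], 100)), rowMeans(matrix(Tn$E[m, ], 100))), 0)
  expect_true(all(prof_cors > 0.99))
})

test_that("mismatched synergy configuration is rejected", {
  expect_error(ground_truth(k = 5, W = matrix(1, 11, 4)), "W must be")
  expect_error(ground_truth(k = 5, profile_centers = c(10, 20)), "match k")
  expect_error(ground_truth(n_strides = 0), "n_strides")
})

test_that("cohort manifests lay out the full 3 x 2 design", {
  ch <- gen_cohort(1, seed = 5, n_strides = 2)
  expect_equal(nrow(ch$manifest), 6L)
  expect_setequal(ch$manifest$time_point, c("Pre", "Post1", "Post2"))
  expect_setequal(ch$manifest$condition, c("normal", "narrow"))
  ch2 <- gen_cohort(3, seed = 5, n_strides = 2)
  expect_equal(nrow(ch2$manifest), 18L)
  ## per-trial ground truth is stored and scoreable without materialization
  expect_length(ch2$gts, 18L)
  expect_s3_class(ch2$gts[[1]], "gait_ground_truth")
  ## same master seed reproduces the manifest exactly
  ch3 <- gen_cohort(3, seed = 5, n_strides = 2)
  expect_identical(ch2$manifest, ch3$manifest)
})

test_that("imposed step-width effects shift the targeted cell only", {
  eff <- list(step_width = matrix(c(0, 0, 0, 0, 0, -0.02), 3, 2))
  ch0 <- gen_cohort(6, seed = 21, n_strides = 2)
  ch1 <- gen_cohort(6, effects = eff, seed = 21, n_strides = 2)
  m0 <- ch0$manifest; m1 <- ch1$manifest
  tgt <- m0$time_point == "Post2" & m0$condition == "narrow"
  expect_equal(m1$step_width_mean[tgt], m0$step_width_mean[tgt] - 0.02)
  expect_equal(m1$step_width_mean[!tgt], m0$step_width_mean[!tgt])
})
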