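# NNMF extraction, k selection, fixed-weighting fits, FWHM/CoA and matching.

## small exact factorization fixture
mk_exact <- function(k = 3, ncol = 300, seed = 1) {
  withr::with_seed(seed, {
    W0 <- matrix(runif(11 * k), 11, k)
    A0 <- matrix(runif(k * ncol), k, ncol)
  })
  list(E = W0 %*% A0, W = W0, A = A0)
}

test_that("an exactly factorizable matrix is recovered to VAF ~ 1", {
  fx <- mk_exact()
  fit <- nnmf(fx$E, 3, restarts = 8, seed = 2)
  expect_gte(fit$vaf, 0.999)
  expect_true(all(fit$W >= 0) && all(fit$A >= 0))
  expect_equal(unname(apply(fit$W, 2, max)), rep(1, 3))
  ## rank-1
  r1 <- mk_exact(k = 1)
  expect_gte(nnmf(r1$E, 1, restarts = 3, seed = 2)$vaf, 0.999)
})

test_that("invalid factorization inputs are rejected", {
  fx <- mk_exact()
  expect_error(nnmf(-fx$E, 2), "nonnegative")
  expect_error(nnmf(fx$E, 12), "exceed")
  bad <- fx$E; bad[3, ] <- 0
  expect_error(nnmf(bad, 2), "all-zero")
})

test_that("VAF is non-decreasing in k under restart reuse", {
  fx <- mk_exact(k = 4, ncol = 400, seed = 5)
  E <- fx$E + matrix(runif(length(fx$E), 0, 0.15), nrow = 11)
  k <- select_k(E, vaf_min = 0.995, restarts = 4, seed = 3)
  vafs <- attr(k, "vaf")
  expect_true(all(diff(vafs) >= -1e-6))
  expect_equal(as.integer(k), which(vafs >= 0.995)[1])
  ## threshold unreachable within k_max
  expect_error(select_k(E, vaf_min = 0.99999, restarts = 2, seed = 3,
                        k_max = 2), "no k")
})

test_that("FWHM counts samples above the min-subtracted half maximum", {
  pulse <- rep(0, 100); pulse[31:50] <- 1
  expect_equal(attr(synergy_fwhm(pulse), "mean"), 20)
  ## additive baseline does not change it
  expect_equal(attr(synergy_fwhm(pulse + 0.5), "mean"), 20)
  expect_equal(attr(synergy_fwhm(3.7 * pulse), "mean"), 20)
  ## discretized Gaussian bump, sigma = 5: samples with |t - c| < sigma *
  ## sqrt(2 log 2) = 5.887 -> 11 of them
  g <- exp(-((0:99) - 50)^2 / (2 * 25))
  expect_equal(attr(synergy_fwhm(g), "mean"),
               sum(abs((0:99) - 50) < 5 * sqrt(2 * log(2))))
  ## flat profile -> 0
  expect_equal(attr(synergy_fwhm(rep(2, 100)), "mean"), 0)
  ## per-stride values averaged arithmetically
  two <- c(pulse, rep(0, 100)); two[101:110] <- 1
  expect_equal(attr(synergy_fwhm(two), "mean"), 15)
})

test_that("CoA is the circular first-moment angle of the profile", {
  one <- rep(0, 100); one[1] <- 1        # single sample at t = 0
  expect_equal(attr(synergy_coa(one), "mean"), 0)
  ## symmetric bump centred at sample 25 -> pi / 2 exactly
  bump <- exp(-pmin(abs((0:99) - 25), 100 - abs((0:99) - 25))^2 / 18)
  expect_equal(attr(synergy_coa(bump), "mean"), pi / 2, tolerance = 1e-12)
  ## amplitude scaling leaves it unchanged
  expect_equal(synergy_coa(3 * bump), synergy_coa(bump), ignore_attr = TRUE)
  ## zero resultant (balanced opposite masses) is undefined
  opp <- rep(0, 100); opp[c(1, 51)] <- 1
  expect_error(synergy_coa(opp), "resultant")
})

test_that("circularly shifting a profile shifts CoA by 2 pi s / 100", {
  withr::with_seed(7, {
    for (r in 1:100) {
      prof <- runif(100) + 2 * exp(-((0:99) - sample(0:99, 1))^2 / 50)
      s <- sample(0:99, 1)
      shifted <- prof[((0:99 - s) %% 100) + 1]
      d <- (attr(synergy_coa(shifted), "mean") -
              attr(synergy_coa(prof), "mean") - 2 * pi * s / 100) %% (2 * pi)
      expect_lt(min(d, 2 * pi - d), 1e-9)
    }
  })
})

test_that("synergy matching solves the assignment exactly", {
  fx <- mk_exact(k = 5, ncol = 50, seed = 9)
  expect_equal(as.integer(match_synergies(fx$W, fx$W)), 1:5)
  perm <- c(3, 1, 4, 5, 2)
  expect_equal(as.integer(match_synergies(fx$W, fx$W[, perm])),
               order(perm))
  ## noisy copy: agrees with the exhaustive permutation oracle
  withr::with_seed(10, Wn <- pmax(fx$W[, perm] + matrix(rnorm(55, 0, 0.1), 11), 0))
  expect_equal(as.integer(match_synergies(fx$W, Wn)),
               brute_force_match(fx$W, Wn))
})

test_that("fixed-weighting fits share W and slice activations per block", {
  ## blocks built from one W with block-specific bump placement
  withr::with_seed(11, W0 <- matrix(runif(11 * 3, 0.05, 1), 11, 3))
  mk_block <- function(centers) {
    A <- t(sapply(centers, function(c0)
      rep(exp(-pmin(abs((0:99) - c0), 100 - abs((0:99) - c0))^2 / 32), 2)))
    W0 %*% A
  }
  blocks <- list(a = mk_block(c(10, 40, 70)), b = mk_block(c(20, 50, 80)))
  fit <- fit_fixed_w(blocks, k = 3, restarts = 10, seed = 13)
  expect_equal(ncol(fit$A$a), 200L)
  expect_equal(ncol(fit$A$b), 200L)
  expect_gte(fit$vaf, 0.99)
  ## block-specific peak locations recovered: per fitted synergy the peak of
  ## block b lags block a by 10 samples
  pk <- function(v) which.max(rowMeans(matrix(v, nrow = 100))) - 1L
  perm <- match_synergies(W0, fit$W)
  for (j in 1:3) {
    sh <- (pk(fit$A$b[perm[j], ]) - pk(fit$A$a[perm[j], ])) %% 100
    expect_lt(min(abs(sh - 10), abs(sh - 110)), 3)
  }
  ## permuting block order only permutes the A slices; W converges to the
  ## same optimum (up to the iteration's column-order sensitivity)
  fit2 <- fit_fixed_w(blocks[c("b", "a")], k = 3, restarts = 10, seed = 13)
  expect_equal(fit2$W, fit$W, tolerance = 0.02)
  expect_equal(fit2$A$a, fit$A$a, tolerance = 0.05)
  expect_equal(names(fit2$A), c("b", "a"))
  ## concatenation arithmetic: 6 blocks x 16000 columns -> 96000
  sizes <- rep(16000, 6)
  expect_equal(sum(sizes), 96000)
  ## mismatched muscle dimension is rejected
  expect_error(fit_fixed_w(list(a = blocks$a, b = blocks$b[1:10, ]), 3),
               "muscle")
})

test_that("six-synergy sensitivity configuration runs on the same data", {
  E <- fx_E40()$E
  fit6 <- nnmf(E, 6, restarts = 3, seed = 17, tol = 1e-5)
  expect_equal(fit6$k, 6)
  expect_equal(dim(fit6$W), c(11L, 6L))
  fit5 <- nnmf(E, 5, restarts = 3, seed = 17, tol = 1e-5)
  expect_gte(fit6$vaf, fit5$vaf - 0.01)
})
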