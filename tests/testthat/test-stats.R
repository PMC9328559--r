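# Repeated-measures ANOVA, Holm adjustment, circular statistics.

mk_two_way <- function(n = 12, seed = 1, noise = 0.7) {
  withr::with_seed(seed, {
    d <- expand.grid(subject = sprintf("S%02d", 1:n),
                     A = c("Pre", "Post1", "Post2"),
                     B = c("normal", "narrow"), stringsAsFactors = FALSE)
    subj <- rnorm(n)[as.integer(factor(d$subject))]
    lev <- as.integer(factor(d$A, levels = c("Pre", "Post1", "Post2")))
    d$y <- subj + 0.5 * lev + (lev == 3) * rnorm(nrow(d), 0, 1.5) +
      rnorm(nrow(d), 0, noise) + ifelse(d$B == "narrow", -0.4, 0)
    d
  })
}

test_that("one-way RM-ANOVA matches direct sums-of-squares enumeration", {
  withr::with_seed(3, {
    Y <- matrix(rnorm(30), 10, 3) + outer(rnorm(10), rep(1, 3)) +
      outer(rep(1, 10), c(0, 0.4, 0.9))
  })
  d <- data.frame(subject = rep(sprintf("S%02d", 1:10), 3),
                  A = rep(c("a", "b", "c"), each = 10),
                  y = as.vector(Y))
  an <- rm_anova(d, dv = "y", within = "A")
  oracle <- hand_rm_anova_oneway(Y)
  expect_equal(an$F, oracle$F, tolerance = 1e-8)
  expect_equal(an$df1, oracle$df1)
  expect_equal(an$df2, oracle$df2)
  ## uncorrected p agrees when no correction applied
  if (!an$gg_applied) expect_equal(an$p, oracle$p, tolerance = 1e-8)
})

test_that("two-way RM-ANOVA agrees with the base anova.mlm machinery", {
  d <- mk_two_way()
  an <- rm_anova(d, dv = "y", within = c("A", "B"))
  n <- 12
  ds <- d[order(d$subject, factor(d$A, c("Pre", "Post1", "Post2")),
                factor(d$B, c("normal", "narrow"))), ]
  Y <- matrix(ds$y, nrow = n, byrow = TRUE)
  idata <- expand.grid(B = factor(c("normal", "narrow"),
                                  c("normal", "narrow")),
                       A = factor(c("Pre", "Post1", "Post2"),
                                  c("Pre", "Post1", "Post2")))[, 2:1]
  fit <- lm(Y ~ 1)
  for (mset in list(list(ef = "A", X = ~1, M = ~A),
                    list(ef = "B", X = ~1, M = ~B),
                    list(ef = "A:B", X = ~ A + B, M = ~ A * B))) {
    o <- anova(fit, idata = idata, X = mset$X, M = mset$M, test = "Spherical")
    expect_equal(an$F[an$effect == mset$ef], o["(Intercept)", "F"],
                 tolerance = 1e-8)
    if (mset$ef != "B") {
      mt <- mauchly.test(fit, idata = idata, X = mset$X, M = mset$M)
      expect_equal(an$mauchly_p[an$effect == mset$ef], mt$p.value,
                   tolerance = 1e-8)
    }
  }
  ## our epsilon reproduces base R's Greenhouse-Geisser-corrected p-value
  oA <- anova(fit, idata = idata, X = ~1, M = ~A, test = "Spherical")
  rowA <- an[an$effect == "A", ]
  p_gg <- pf(rowA$F, 2 * rowA$epsilon, 22 * rowA$epsilon, lower.tail = FALSE)
  expect_equal(p_gg, oA["(Intercept)", "G-G Pr"], tolerance = 1e-8)
})

test_that("sphericity handling: 2-level factors are never corrected", {
  d <- mk_two_way(seed = 5)
  an <- rm_anova(d, dv = "y", within = c("A", "B"))
  bb <- an[an$effect == "B", ]
  expect_equal(bb$epsilon, 1)
  expect_false(bb$gg_applied)
  expect_true(is.na(bb$mauchly_p))
  ## when GG fires, both dfs shrink by epsilon
  d2 <- mk_two_way(seed = 11, noise = 0.3)
  an2 <- rm_anova(d2, dv = "y", within = c("A", "B"))
  g <- an2[an2$gg_applied, ]
  if (nrow(g)) expect_true(all(g$df1 < 2 & g$df2 < 22))
})

test_that("degenerate and malformed designs are handled", {
  d <- expand.grid(subject = sprintf("S%d", 1:6), A = c("x", "y", "z"))
  d$y <- rep(rnorm(6), 3)    # identical across levels
  an <- rm_anova(d, dv = "y", within = "A")
  expect_equal(an$F, 0)
  expect_error(rm_anova(d[-1, ], dv = "y", within = "A"), "balanced")
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_posthoc(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_posthoc(0.2), 0.2)
  expect_equal(holm_posthoc(rep(0.02, 4)), rep(min(1, 4 * 0.02), 4))
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(holm_posthoc(p) >= p))
  expect_error(holm_posthoc(c(0.1, 0)), "0, 1")
  expect_error(holm_posthoc(numeric(0)), "at least one")
})

test_that("paired post-hocs detect the imposed Pre-to-Post2 change", {
  withr::with_seed(9, {
    d <- data.frame(subject = rep(sprintf("S%02d", 1:15), 3),
                    tp = rep(c("Pre", "Post1", "Post2"), each = 15))
    d$y <- rnorm(45, 0, 0.3) + rep(rnorm(15), 3) +
      ifelse(d$tp == "Post2", -1, 0)
  })
  ph <- paired_posthoc(d, dv = "y", factor = "tp")
  expect_equal(ph$comparison, c("Pre vs Post1", "Pre vs Post2"))
  expect_lt(ph$p_holm[2], 0.001)
  expect_gt(ph$p_holm[1], 0.05)
  expect_true(all(ph$p_holm >= ph$p_raw))
})

test_that("circular mean behaves on canonical fixtures", {
  expect_equal(circ_mean(c(0, 0)), 0)
  expect_equal(circ_mean(c(pi / 2 - 0.1, pi / 2 + 0.1)), pi / 2)
  ## wrap: mean of angles around 0 stays in [0, 2 pi)
  m <- circ_mean(c(0.1, 2 * pi - 0.1))
  expect_true(m < 0.01 || m > 2 * pi - 0.01)
  expect_error(circ_mean(c(0, pi)), "resultant")
})

test_that("the circular two-way ANOVA matches an equation-level oracle", {
  ## 12-angle fixture, concentrated (F regime)
  ang <- c(0.95, 1.10, 1.02, 1.25, 1.31, 1.18, 0.45, 0.52, 0.61, 0.70,
           0.66, 0.58)
  f1 <- rep(c("t1", "t2"), each = 6)
  f2 <- rep(rep(c("c1", "c2"), each = 3), 2)
  got <- circ_anova2(ang, f1, f2)
  ora <- hk_oracle(ang, f1, f2)
  expect_equal(got$statistic, ora$statistic, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  expect_equal(attr(got, "kappa"), ora$kappa, tolerance = 1e-10)

  ## diffuse fixture exercises the chi-squared regime against the oracle
  withr::with_seed(21, angl <- runif(36, 0, 2 * pi))
  fl1 <- rep(c("a", "b", "c"), each = 12)
  fl2 <- rep(rep(c("x", "y"), each = 6), 3)
  gl <- circ_anova2(angl, fl1, fl2)
  ol <- hk_oracle(angl, fl1, fl2)
  expect_match(gl$method[1], "chi")
  expect_equal(gl$statistic, ol$statistic, tolerance = 1e-10)
  expect_equal(gl$p, ol$p, tolerance = 1e-10)
})

test_that("a condition shift in concentrated angles is detected", {
  withr::with_seed(4, {
    n <- 20
    f1 <- rep(c("Pre", "Post1", "Post2"), each = 2 * n)
    f2 <- rep(rep(c("normal", "narrow"), each = n), 3)
    ## von Mises kappa = 50 corresponds to angular sd ~ 1/sqrt(50)
    ang <- 1.0 + rnorm(length(f1), 0, 1 / sqrt(50))
    ang[f2 == "narrow"] <- ang[f2 == "narrow"] + pi / 4
  })
  res <- circ_anova2(ang, f1, f2)
  expect_lt(res$p[res$effect == "f2"], 0.01)
  expect_gt(res$p[res$effect == "f1"], 0.05)
  ## all-equal angles: statistics 0, p 1
  eq <- circ_anova2(rep(1.2, 60), rep(c("a", "b", "c"), each = 20),
                    rep(rep(c("x", "y"), each = 10), 3))
  expect_equal(eq$statistic, rep(0, 3))
  expect_equal(eq$p, rep(1, 3))
})
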