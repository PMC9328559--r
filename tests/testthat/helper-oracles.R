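# Independent oracles, implemented apart from the package code paths.

## Largest Lyapunov exponent of the Lorenz system by the Benettin method:
## RK4 integration of the flow plus tangent dynamics with renormalization.
## Independent of the package's divergence-curve estimator.
benettin_lorenz <- function(T = 200, dt = 0.005, y0 = c(1, 1, 20)) {
  f <- function(y) c(10 * (y[2] - y[1]),
                     y[1] * (28 - y[3]) - y[2],
                     y[1] * y[2] - 8 / 3 * y[3])
  J <- function(y) matrix(c(-10, 10, 0,
                            28 - y[3], -1, -y[1],
                            y[2], y[1], -8 / 3), 3, 3, byrow = TRUE)
  rk4 <- function(y, h, fun) {
    k1 <- fun(y); k2 <- fun(y + h / 2 * k1)
    k3 <- fun(y + h / 2 * k2); k4 <- fun(y + h * k3)
    y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y <- y0
  for (i in seq_len(4000)) y <- rk4(y, dt, f)   # transient
  v <- c(1, 0, 0); s <- 0
  fun <- function(z) c(f(z[1:3]), J(z[1:3]) %*% z[4:6])
  for (i in seq_len(round(T / dt))) {
    z <- rk4(c(y, v), dt, fun)
    y <- z[1:3]; v <- z[4:6]
    nv <- sqrt(sum(v^2)); s <- s + log(nv); v <- v / nv
  }
  s / T
}

## One-way fully-within ANOVA by direct sums-of-squares enumeration.
## Y: subjects x levels matrix.
hand_rm_anova_oneway <- function(Y) {
  n <- nrow(Y); a <- ncol(Y)
  gm <- mean(Y)
  m_lev <- colMeans(Y); m_sub <- rowMeans(Y)
  ss_a <- n * sum((m_lev - gm)^2)
  ss_err <- sum((Y - outer(m_sub, rep(1, a)) -
                   outer(rep(1, n), m_lev) + gm)^2)
  Fv <- (ss_a / (a - 1)) / (ss_err / ((a - 1) * (n - 1)))
  list(F = Fv, df1 = a - 1, df2 = (a - 1) * (n - 1),
       p = pf(Fv, a - 1, (a - 1) * (n - 1), lower.tail = FALSE))
}

## Harrison-Kanji two-factor circular ANOVA, re-implemented with scalar
## loops directly from the test equations (high-concentration F regime and
## low-concentration chi-squared regime).
hk_oracle <- function(angles, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  p <- nlevels(f1); q <- nlevels(f2); n <- length(angles)
  R <- function(a) {
    C <- 0; S <- 0
    for (x in a) { C <- C + cos(x); S <- S + sin(x) }
    sqrt(C^2 + S^2)
  }
  tr <- R(angles)
  rbar <- tr / n
  kk <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
  else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)

  pr <- pn <- numeric(p); qr <- qn <- numeric(q)
  grs <- 0
  for (i in seq_len(p)) {
    sel <- f1 == levels(f1)[i]
    pn[i] <- sum(sel); pr[i] <- R(angles[sel])
  }
  for (j in seq_len(q)) {
    sel <- f2 == levels(f2)[j]
    qn[j] <- sum(sel); qr[j] <- R(angles[sel])
  }
  for (i in seq_len(p)) for (j in seq_len(q)) {
    sel <- f1 == levels(f1)[i] & f2 == levels(f2)[j]
    grs <- grs + R(angles[sel])^2 / sum(sel)
  }
  e1 <- sum(pr^2 / pn) - tr^2 / n
  e2 <- sum(qr^2 / qn) - tr^2 / n
  ei <- grs - sum(pr^2 / pn) - sum(qr^2 / qn) + tr^2 / n
  d1 <- p - 1; d2 <- q - 1; d12 <- d1 * d2
  if (kk > 2) {
    beta <- 1 / (1 - 1 / (5 * kk) - 1 / (10 * kk^2))
    er <- n - grs
    dr <- n - p * q
    msr <- er / dr
    Fs <- c(beta * (e1 / d1) / msr, beta * (e2 / d2) / msr, (ei / d12) / msr)
    ps <- pf(Fs, c(d1, d2, d12), dr, lower.tail = FALSE)
  } else {
    rr <- besselI(kk, 1) / besselI(kk, 0)
    fac <- 2 / (1 - rr^2)
    Fs <- fac * c(e1, e2, ei)
    ps <- pchisq(Fs, c(d1, d2, d12), lower.tail = FALSE)
  }
  list(statistic = Fs, p = ps, kappa = kk)
}

## Exhaustive assignment oracle: best column matching by total cosine
## similarity over all permutations (k <= 7).
brute_force_match <- function(Wa, Wb) {
  k <- ncol(Wa)
  stopifnot(k <= 7)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- NULL; best_s <- -Inf
  for (p in perms(seq_len(k))) {
    s <- sum(vapply(seq_len(k), function(j) cs(Wa[, j], Wb[, p[j]]), 0))
    if (s > best_s) { best_s <- s; best <- p }
  }
  best
}
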