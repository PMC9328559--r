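# Statistical layer: repeated-measures ANOVA with Greenhouse-Geisser
# correction and Holm post-hocs, plus circular statistics (circular mean,
# Harrison-Kanji two-way ANOVA for angles).

## Orthonormal contrast basis orthogonal to the intercept (levels x levels-1).
ortho_contrasts <- function(levels) {
  C <- stats::contr.helmert(levels)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

## Greenhouse-Geisser epsilon and Mauchly sphericity test from the
## subject x cell matrix Y and an orthonormal effect-contrast matrix C.
sphericity <- function(Y, C) {
  d <- ncol(C)
  n <- nrow(Y)
  Sc <- t(C) %*% stats::cov(Y) %*% C
  eps <- sum(diag(Sc))^2 / (d * sum(Sc^2))
  if (d < 2) return(list(eps = 1, W = NA_real_, p = NA_real_))
  W <- det(Sc) / (sum(diag(Sc)) / d)^d
  if (!is.finite(W) || W <= 0) return(list(eps = eps, W = W, p = 0))
  chi2 <- -((n - 1) - (2 * d^2 + d + 2) / (6 * d)) * log(W)
  p <- stats::pchisq(chi2, d * (d + 1) / 2 - 1, lower.tail = FALSE)
  list(eps = eps, W = W, p = p)
}

#' Repeated-measures ANOVA (fully within-subject, one or two factors)
#'
#' Classical univariate within-subject ANOVA on a balanced complete design:
#' sums of squares via [stats::aov()] Error strata, Mauchly's sphericity test
#' per effect with more than two levels, and Greenhouse-Geisser scaling of
#' both degrees of freedom when sphericity is rejected (Mauchly p <
#' `sphericity_alpha`).
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject-identifier column.
#' @param within character vector of one or two within-subject factor names.
#' @param sphericity_alpha Mauchly p-value below which the correction is
#'   applied.
#' @return data.frame with one row per effect: `effect`, `F`, `df1`, `df2`
#'   (Greenhouse-Geisser-scaled when applied), `epsilon`, `gg_applied`,
#'   `mauchly_p`, `p`.
#' @export
rm_anova <- function(data, dv, subject = "subject", within,
                     sphericity_alpha = 0.05) {
  stopifnot(length(within) %in% 1:2, all(c(dv, subject, within) %in% names(data)))
  d <- data.frame(y = data[[dv]],
                  subject = factor(data[[subject]]))
  for (i in seq_along(within)) d[[paste0("f", i)]] <- factor(data[[within[i]]])
  nfac <- length(within)
  cells <- interaction(d[paste0("f", seq_len(nfac))], drop = FALSE)
  tab <- table(d$subject, cells)
  if (any(tab != 1)) stop("design must be balanced and complete: one observation per subject per cell")

  fml <- if (nfac == 1) y ~ f1 + Error(subject / f1)
         else y ~ f1 * f2 + Error(subject / (f1 * f2))
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)

  effects <- if (nfac == 1) "f1" else c("f1", "f2", "f1:f2")
  labels <- if (nfac == 1) within else c(within, paste(within, collapse = ":"))
  a <- nlevels(d$f1)
  b <- if (nfac == 2) nlevels(d$f2) else 1L
  Ca <- ortho_contrasts(a)
  Cb <- if (nfac == 2) ortho_contrasts(b) else NULL

  ## subject x cell matrix, cells ordered f1 (slow) x f2 (fast)
  ord <- if (nfac == 2) order(d$subject, d$f1, d$f2) else order(d$subject, d$f1)
  Y <- matrix(d$y[ord], nrow = nlevels(d$subject), byrow = TRUE)

  out <- lapply(seq_along(effects), function(i) {
    ef <- effects[i]
    ## locate the stratum whose table contains this effect
    row <- NULL
    for (s in sm) {
      tb <- s[[1]]
      hit <- trimws(rownames(tb)) == ef
      if (any(hit)) { row <- tb[hit, , drop = FALSE]; err <- tb[trimws(rownames(tb)) == "Residuals", , drop = FALSE] }
    }
    if (is.null(row)) stop("effect ", ef, " not found in ANOVA strata")
    Fv <- row[1, "F value"]
    ## no effect variance at all (identical values across levels): F = 0
    ss_scale <- sum((d$y - mean(d$y))^2) + .Machine$double.eps
    if (row[1, "Sum Sq"] <= 1e-12 * ss_scale) Fv <- 0
    df1 <- row[1, "Df"]; df2 <- err[1, "Df"]

    ## effect-specific contrast of the per-subject cell vectors
    C <- switch(ef,
                "f1" = if (nfac == 2) kronecker(Ca, matrix(1 / sqrt(b), b, 1)) else Ca,
                "f2" = kronecker(matrix(1 / sqrt(a), a, 1), Cb),
                "f1:f2" = kronecker(Ca, Cb))
    sp <- sphericity(Y, C)
    gg <- df1 > 1 && is.finite(sp$p) && sp$p < sphericity_alpha
    if (gg) { df1 <- df1 * sp$eps; df2 <- df2 * sp$eps }
    data.frame(effect = labels[i], F = Fv, df1 = df1, df2 = df2,
               epsilon = sp$eps, gg_applied = gg, mauchly_p = sp$p,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Holm step-down adjustment of p-values
#'
#' Thin wrapper around [stats::p.adjust()] with input validation; adjusted
#' p-values are always at least the raw values and monotone in rank.
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values in input order.
#' @export
holm_posthoc <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Paired-t post-hoc comparisons with Holm correction
#'
#' Paired t-tests between levels of a within-subject factor, Holm-adjusted
#' as one family (the study's family: Pre vs Post1 and Pre vs Post2).
#'
#' @param data long-format data.frame (one observation per subject x level).
#' @param dv,subject,factor column names.
#' @param comparisons list of length-2 character vectors of level pairs.
#' @return data.frame with `comparison`, `t`, `df`, `p_raw`, `p_holm`.
#' @export
paired_posthoc <- function(data, dv, subject = "subject", factor,
                           comparisons = list(c("Pre", "Post1"),
                                              c("Pre", "Post2"))) {
  res <- lapply(comparisons, function(cp) {
    d1 <- data[data[[factor]] == cp[1], c(subject, dv)]
    d2 <- data[data[[factor]] == cp[2], c(subject, dv)]
    m <- merge(d1, d2, by = subject, suffixes = c(".1", ".2"))
    tt <- stats::t.test(m[[paste0(dv, ".1")]], m[[paste0(dv, ".2")]],
                        paired = TRUE)
    data.frame(comparison = paste(cp, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_posthoc(out$p_raw)
  out
}

#' Circular mean of angles
#'
#' Angle of the summed unit vectors, wrapped to \[0, 2 pi). Errors when the
#' resultant length is (numerically) zero, in which case the mean direction
#' is undefined.
#'
#' @param angles numeric vector of angles in radians.
#' @return circular mean in \[0, 2 pi).
#' @export
circ_mean <- function(angles) {
  if (!length(angles)) stop("need at least one angle")
  s <- sum(sin(angles)); c <- sum(cos(angles))
  if (sqrt(s^2 + c^2) / length(angles) < 1e-12)
    stop("circular mean undefined: zero resultant length")
  wrap_angle(atan2(s, c))
}

## Mean resultant length.
circ_r <- function(angles) {
  sqrt(sum(sin(angles))^2 + sum(cos(angles))^2) / length(angles)
}

## Maximum-likelihood von Mises concentration from a mean resultant length
## (Fisher's approximations).
circ_kappa <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Harrison-Kanji two-way ANOVA for circular data
#'
#' Parametric two-factor analysis of variance for angles. The total
#' concentration is estimated from the overall mean resultant length; for
#' concentrated data (kappa > 2) F statistics with a high-concentration bias
#' correction are used, otherwise chi-squared statistics based on the large-
#' sample approximation.
#'
#' @param angles numeric vector of angles in radians.
#' @param f1,f2 factors (or coercible) of the two crossed effects.
#' @return data.frame with rows for both main effects and the interaction:
#'   `effect`, `df1`, `df2` (NA for the chi-squared regime), `statistic`,
#'   `p`, `method`; the estimated kappa is attached as attribute `"kappa"`.
#' @export
circ_anova2 <- function(angles, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  stopifnot(length(angles) == length(f1), length(angles) == length(f2))
  p <- nlevels(f1); q <- nlevels(f2); n <- length(angles)
  if (p < 2 || q < 2) stop("both factors need at least two levels")

  tr <- n * circ_r(angles)
  kk <- circ_kappa(tr / n)

  ## no angular spread at all: every effect is exactly null
  if (n - tr^2 / n < 1e-10 * n) {
    p <- nlevels(f1); q <- nlevels(f2)
    out <- data.frame(effect = c("f1", "f2", "f1:f2"),
                      df1 = c(p - 1, q - 1, (p - 1) * (q - 1)),
                      df2 = NA_real_, statistic = 0, p = 1,
                      method = "degenerate (zero spread)")
    attr(out, "kappa") <- kk
    return(out)
  }

  gn <- matrix(0, p, q); gr <- matrix(0, p, q)
  for (i in seq_len(p)) for (j in seq_len(q)) {
    id <- f1 == levels(f1)[i] & f2 == levels(f2)[j]
    gn[i, j] <- sum(id)
    gr[i, j] <- if (any(id)) sum(id) * circ_r(angles[id]) else 0
  }
  if (any(gn == 0)) stop("empty design cell")
  if (any(gr / gn < 1e-8))
    warning("near-zero resultant length in a design cell; test assumptions violated")
  pn <- rowSums(gn); qn <- colSums(gn)
  pr <- vapply(seq_len(p), function(i) pn[i] * circ_r(angles[f1 == levels(f1)[i]]), 0)
  qr <- vapply(seq_len(q), function(j) qn[j] * circ_r(angles[f2 == levels(f2)[j]]), 0)

  df1v <- p - 1; df2v <- q - 1; df12 <- (p - 1) * (q - 1)
  eff_1 <- sum(pr^2 / pn) - tr^2 / n
  eff_2 <- sum(qr^2 / qn) - tr^2 / n

  if (kk > 2) {
    ## high-concentration regime: F statistics with bias correction
    beta <- 1 / (1 - 1 / (5 * kk) - 1 / (10 * kk^2))
    eff_r <- n - sum(gr^2 / gn)
    df_r <- n - p * q
    ms_r <- eff_r / df_r
    eff_i <- sum(gr^2 / gn) - sum(pr^2 / pn) - sum(qr^2 / qn) + tr^2 / n
    FI <- (eff_i / df12) / ms_r
    F1 <- beta * (eff_1 / df1v) / ms_r
    F2 <- beta * (eff_2 / df2v) / ms_r
    out <- data.frame(
      effect = c("f1", "f2", "f1:f2"),
      df1 = c(df1v, df2v, df12), df2 = rep(df_r, 3),
      statistic = c(F1, F2, FI),
      p = stats::pf(c(F1, F2, FI), c(df1v, df2v, df12), df_r, lower.tail = FALSE),
      method = "F (high concentration)")
  } else {
    ## low-concentration regime: chi-squared statistics
    rr <- besselI(kk, 1) / besselI(kk, 0)
    fac <- 2 / (1 - rr^2)
    chi1 <- fac * eff_1
    chi2 <- fac * eff_2
    chiI <- fac * (sum(gr^2 / gn) - sum(pr^2 / pn) - sum(qr^2 / qn) + tr^2 / n)
    out <- data.frame(
      effect = c("f1", "f2", "f1:f2"),
      df1 = c(df1v, df2v, df12), df2 = NA_real_,
      statistic = c(chi1, chi2, chiI),
      p = stats::pchisq(c(chi1, chi2, chiI), c(df1v, df2v, df12),
                        lower.tail = FALSE),
      method = "chi-squared (low concentration)")
  }
  ## degenerate limit (e.g. all angles equal): zero effect over zero residual
  eff_num <- c(eff_1, eff_2, sum(gr^2 / gn) - sum(pr^2 / pn) - sum(qr^2 / qn) + tr^2 / n)
  deg <- !is.finite(out$statistic) & abs(eff_num) < 1e-10
  out$statistic[deg] <- 0
  out$p[deg] <- 1
  attr(out, "kappa") <- kk
  out
}
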