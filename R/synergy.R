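# Muscle synergy extraction by non-negative matrix factorization
# (Lee-Seung multiplicative updates, squared Frobenius objective) and the
# activation-timing metrics FWHM and CoA.

#' Non-negative matrix factorization of an activation matrix
#'
#' Multiplicative-update NMF with multiple random restarts. Each restart is
#' initialized with uniform(0, 1\] entries from a seed stream derived from
#' `seed`; updates stop when the relative decrease of the squared Frobenius
#' reconstruction error falls below `tol` or after `max_iter` iterations.
#' The restart with the lowest reconstruction error is returned, with W
#' columns max-normalized to 1 and the activations rescaled inversely (the
#' product W A is invariant).
#'
#' @param E nonnegative muscles x samples matrix.
#' @param k number of synergies (<= number of muscles).
#' @param restarts number of random restarts (study value 50).
#' @param max_iter maximum multiplicative updates per restart (study 1000).
#' @param tol relative objective-decrease tolerance (study 1e-6).
#' @param seed master seed for the restart initializations.
#' @param init optional list of extra initializations, each
#'   `list(W =, H =)`, tried in addition to the random restarts.
#' @return object of class `synergy_model`: `W` (muscles x k), `A`
#'   (k x samples), `vaf`, `k`, `rep_errors` (per-restart final objectives),
#'   `iters`.
#' @export
nnmf <- function(E, k, restarts = 50L, max_iter = 1000L, tol = 1e-6,
                 seed = 1L, init = NULL) {
  stopifnot(is.matrix(E))
  if (any(E < 0)) stop("E must be nonnegative")
  if (any(apply(E, 1, function(r) all(r == 0)))) stop("E has all-zero rows")
  if (k > nrow(E)) stop("k must not exceed the number of muscles (rows)")
  n <- nrow(E); p <- ncol(E)
  seeds <- derive_seeds(seed, restarts)
  inits <- lapply(seq_len(restarts), function(r)
    local_seed(seeds[r], list(W = matrix(runif(n * k), n, k),
                              H = matrix(runif(k * p), k, p))))
  inits <- c(inits, init)
  best <- NULL
  errs <- numeric(length(inits))
  iters <- integer(length(inits))
  for (r in seq_along(inits)) {
    fit <- .nmf_mu(E, inits[[r]]$W, inits[[r]]$H, max_iter, tol)
    errs[r] <- fit$obj
    iters[r] <- fit$iters
    if (is.null(best) || fit$obj < best$obj) best <- fit
  }
  W <- best$W; A <- best$H
  scl <- apply(W, 2, max)
  scl[scl == 0] <- 1
  W <- sweep(W, 2, scl, "/")
  A <- A * scl  # row-wise rescale: column scaling of W <-> row scaling of A
  rownames(W) <- rownames(E)
  vaf <- 1 - sum((E - W %*% A)^2) / sum(E^2)
  structure(list(W = W, A = A, vaf = vaf, k = k, rep_errors = errs,
                 iters = iters),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> k = %d, VAF = %.3f (%d restarts)\n",
              x$k, x$vaf, length(x$rep_errors)))
  invisible(x)
}

#' Select the number of synergies by a VAF threshold
#'
#' Returns the smallest k whose variance accounted for reaches `vaf_min`
#' (study threshold: 85 %). Each k is warm-started from the previous k's
#' solution (augmented with a random component) in addition to its random
#' restarts, which keeps the VAF curve non-decreasing in k.
#'
#' @inheritParams nnmf
#' @param vaf_min VAF threshold in (0, 1).
#' @param k_max largest k to try.
#' @return integer k, with the VAF curve attached as attribute `"vaf"`.
#' @export
select_k <- function(E, vaf_min = 0.85, restarts = 10L, max_iter = 1000L,
                     tol = 1e-6, seed = 1L, k_max = nrow(E)) {
  stopifnot(vaf_min > 0, vaf_min < 1)
  vafs <- numeric(0)
  prev <- NULL
  for (k in seq_len(k_max)) {
    init <- NULL
    if (!is.null(prev)) {
      aug <- local_seed(seed + k, list(
        W = cbind(prev$W, matrix(runif(nrow(E)), ncol = 1)),
        H = rbind(prev$A, matrix(runif(ncol(E)), nrow = 1))))
      init <- list(aug)
    }
    fit <- nnmf(E, k, restarts = restarts, max_iter = max_iter, tol = tol,
                seed = seed + k, init = init)
    vafs[k] <- fit$vaf
    prev <- fit
    if (fit$vaf >= vaf_min) return(structure(k, vaf = vafs))
  }
  stop("no k <= ", k_max, " reaches VAF ", vaf_min,
       " (best ", round(max(vafs), 3), ")")
}

#' Factorize concatenated blocks with fixed muscle weightings
#'
#' Concatenates the per-block activation matrices column-wise (e.g. the
#' 3 time-points x 2 conditions of one subject), performs a single
#' factorization so the muscle weightings W are shared, and slices the
#' activation profiles back per block in the input order.
#'
#' @param blocks named list of nonnegative muscles x samples matrices with
#'   identical row order.
#' @param k number of synergies.
#' @param ... passed to [nnmf()].
#' @return list with `W` (shared weightings), `A` (named list of per-block
#'   activations), `vaf` (of the concatenated fit), `model`.
#' @export
fit_fixed_w <- function(blocks, k, ...) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  rn <- lapply(blocks, rownames)
  if (length(unique(vapply(blocks, nrow, 0L))) != 1)
    stop("blocks must share the muscle dimension")
  if (!all(vapply(rn, identical, TRUE, y = rn[[1]])))
    stop("blocks must share muscle order")
  ncols <- vapply(blocks, ncol, 0L)
  Econcat <- do.call(cbind, blocks)
  model <- nnmf(Econcat, k, ...)
  idx <- cumsum(c(0L, ncols))
  A <- lapply(seq_along(blocks), function(i)
    model$A[, (idx[i] + 1L):idx[i + 1L], drop = FALSE])
  names(A) <- names(blocks)
  list(W = model$W, A = A, vaf = model$vaf, model = model)
}

#' Full width at half maximum of an activation profile
#'
#' For each stride slice, the number of samples exceeding half of the
#' min-subtracted maximum: count of a(t) - min > 0.5 (max - min). A flat
#' slice is defined as 0. Invariant to amplitude scaling and additive
#' baselines.
#'
#' @param profile activation profile, either one stride (length
#'   `per_stride`) or a concatenation of strides.
#' @param per_stride samples per stride.
#' @return vector of per-stride FWHM values (samples, i.e. % gait cycle),
#'   with the arithmetic mean over strides as attribute `"mean"`.
#' @export
synergy_fwhm <- function(profile, per_stride = 100L) {
  stopifnot(length(profile) %% per_stride == 0)
  slices <- matrix(profile, nrow = per_stride)
  v <- apply(slices, 2, function(a) {
    rng <- max(a) - min(a)
    if (rng == 0) return(0)
    sum(a - min(a) > 0.5 * rng)
  })
  structure(v, mean = mean(v))
}

#' Centre of activity of an activation profile
#'
#' Treats the gait cycle as a circle (sample t at angle 2 pi t / per_stride,
#' first sample at angle 0) and returns the angle of the activation's first
#' circular moment, wrapped to \[0, 2 pi). Per-stride angles are aggregated
#' by the circular mean.
#'
#' @inheritParams synergy_fwhm
#' @return vector of per-stride CoA angles (radians), with the circular mean
#'   over strides as attribute `"mean"`.
#' @export
synergy_coa <- function(profile, per_stride = 100L) {
  stopifnot(length(profile) %% per_stride == 0)
  slices <- matrix(profile, nrow = per_stride)
  theta <- 2 * pi * (seq_len(per_stride) - 1L) / per_stride
  v <- apply(slices, 2, function(a) {
    s <- sum(a * sin(theta)); c <- sum(a * cos(theta))
    if (s^2 + c^2 < .Machine$double.eps^2 * sum(a)^2 || sum(a) == 0)
      stop("centre of activity undefined: zero resultant length")
    wrap_angle(atan2(s, c))
  })
  structure(v, mean = circ_mean(v))
}

#' Match synergies between two models
#'
#' Exact assignment (Hungarian-equivalent, solved by dynamic programming over
#' column subsets) maximizing the summed cosine similarity of muscle-weighting
#' columns. Ties break deterministically toward lower column indices.
#'
#' @param model_a,model_b `synergy_model` objects or weighting matrices with
#'   equal column counts.
#' @return integer permutation `p` such that column j of `model_a` matches
#'   column `p[j]` of `model_b`; the matched cosine similarities are attached
#'   as attribute `"cosine"`.
#' @export
match_synergies <- function(model_a, model_b) {
  Wa <- if (inherits(model_a, "synergy_model")) model_a$W else model_a
  Wb <- if (inherits(model_b, "synergy_model")) model_b$W else model_b
  stopifnot(ncol(Wa) == ncol(Wb))
  k <- ncol(Wa)
  norm_a <- sqrt(colSums(Wa^2)); norm_b <- sqrt(colSums(Wb^2))
  S <- crossprod(Wa, Wb) / (outer(norm_a, norm_b))
  S[!is.finite(S)] <- 0
  ## DP over subsets of b-columns: best[m+1] = max score assigning a-columns
  ## 1..j to subset m. Exact for k <= ~20.
  nset <- bitwShiftL(1L, k)
  best <- rep(-Inf, nset); best[1] <- 0
  choice <- matrix(NA_integer_, nset, 1)
  from <- rep(NA_integer_, nset)
  pick <- rep(NA_integer_, nset)
  for (m in seq_len(nset - 1L)) {
    j <- sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0)  # popcount = a-col index
    for (b in seq_len(k)) {
      bit <- bitwShiftL(1L, b - 1L)
      if (bitwAnd(m, bit) == 0) next
      prev <- bitwXor(m, bit)
      cand <- best[prev + 1L] + S[j, b]
      if (cand > best[m + 1L] + 1e-15) {
        best[m + 1L] <- cand; from[m + 1L] <- prev; pick[m + 1L] <- b
      }
    }
  }
  perm <- integer(k)
  m <- nset - 1L
  while (m > 0L) {
    j <- sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0)
    perm[j] <- pick[m + 1L]
    m <- from[m + 1L]
  }
  structure(perm, cosine = S[cbind(seq_len(k), perm)])
}
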