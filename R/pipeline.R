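# Pipeline orchestration: trial -> metrics -> cohort statistics.

#' Default pipeline configuration
#'
#' All stage parameters in one serializable list; a run is reproducible from
#' (config, data, seed). Values default to the study protocol: 30 s initial
#' trim, 160 strides, 100 samples/stride, 50 Hz high-pass (order 4), 1 Hz
#' notches at 50 Hz and harmonics (order 1), 20 Hz envelope low-pass
#' (order 2), 5 synergies with 50 NNMF restarts (max 1000 iterations,
#' tolerance 1e-6, VAF threshold 0.85), Rosenstein embedding dim 5 / delay
#' 10 with a half-stride (50-sample) fit window and exclusion window.
#'
#' @param ... overrides of individual entries.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    trim_s = 30, n_strides = 160L, samples_per_stride = 100L,
    hp_cutoff = 50, hp_order = 4, notch_base = 50, notch_bw = 1,
    notch_order = 1, lp_cutoff = 20, lp_order = 2,
    k = 5L, restarts = 50L, max_iter = 1000L, tol = 1e-6, vaf_min = 0.85,
    dim = 5L, delay = 10L, exclusion_window = 50L, horizon = 100L,
    fit_window = 50L, min_event_sep = 0.4, seed = 1L, emg = TRUE)
  utils::modifyList(cfg, list(...))
}

#' Run the per-trial pipeline
#'
#' Trims the habituation period, detects and labels heel strikes from the
#' CoP and foot kinematics, computes gait/stability metrics over the first
#' `n_strides` strides, and (when EMG is present and enabled) the
#' preprocessed stride-normalized activation matrix E for downstream synergy
#' analysis.
#'
#' @param trial a `gait_trial`.
#' @param config a [default_config()] list.
#' @return list with `metrics` (one-row data.frame), `events`, `E`
#'   (`stride_emg` or NULL), `lde` (`stability_result`), `log`.
#' @export
run_trial <- function(trial, config = default_config()) {
  stopifnot(inherits(trial, "gait_trial"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (trial$meta$condition == "narrow" && is.null(trial$beam))
    stop("stage 'validate': beam geometry missing on a narrow-base trial")
  if (config$trim_s > 0) trial <- stage("trim", trim_initial(trial, config$trim_s))
  hs <- stage("events", detect_heelstrikes(trial, min_sep = config$min_event_sep))
  ev <- stage("events", assign_legs(hs, trial))
  gm <- stage("metrics", gait_metrics(trial, ev, n_strides = config$n_strides))
  ld <- stage("stability", stability_lde(trial, ev, n_strides = config$n_strides,
                                         dim = config$dim, delay = config$delay,
                                         exclusion_window = config$exclusion_window,
                                         horizon = config$horizon,
                                         fit_window = config$fit_window))
  E <- NULL
  if (config$emg && !is.null(trial$emg))
    E <- stage("emg", preprocess_emg(trial$emg, trial$fs_emg, ev, config))
  metrics <- data.frame(subject = trial$meta$subject,
                        time_point = trial$meta$time_point,
                        condition = trial$meta$condition,
                        as.data.frame(gm[setdiff(names(gm), "n_strides")]),
                        lde = ld$lde)
  list(metrics = metrics, events = ev, E = E, lde = ld, log = ev$log)
}

#' Run the cohort pipeline
#'
#' Processes every trial, fits per-subject synergies with muscle weightings
#' fixed across the 3 x 2 design (single factorization of the concatenated
#' E blocks), aligns synergy order across subjects against the first
#' subject's weightings, computes FWHM/CoA per synergy and block, and runs
#' the statistical layer: two-way repeated-measures ANOVAs
#' (Training x Condition) on gait metrics and FWHM, one-way ANOVAs on the
#' narrow-base beam scores, Harrison-Kanji circular ANOVAs on CoA, and Holm
#' paired post-hocs for significant training effects or interactions.
#'
#' Subjects with an incomplete 3 x 2 design are dropped (logged); fewer than
#' two complete subjects is an error.
#'
#' @param cohort a [gen_cohort()] object or list of `gait_trial`s.
#' @param config a [default_config()] list.
#' @param W_ref optional reference weighting matrix for synergy alignment
#'   (defaults to the first subject's fitted W).
#' @return list with `metrics` (long, tidy), `timing` (FWHM/CoA long table),
#'   `anova` (named list of data.frames), `posthoc`, `circ` (per synergy),
#'   `W` (per-subject aligned weightings), `vaf` (per subject), `log`.
#' @export
run_cohort <- function(cohort, config = default_config(), W_ref = NULL) {
  trials_meta <- if (inherits(cohort, "gait_cohort")) cohort$manifest else
    do.call(rbind, lapply(cohort, function(tr) as.data.frame(tr$meta[c("subject", "time_point", "condition")])))
  log <- character()

  ## completeness check: 3 time-points x 2 conditions per subject
  keep_subjects <- character()
  for (s in unique(trials_meta$subject)) {
    cells <- trials_meta[trials_meta$subject == s, c("time_point", "condition")]
    full <- nrow(unique(cells)) == 6 && nrow(cells) == 6
    if (full) keep_subjects <- c(keep_subjects, s) else
      log <- c(log, sprintf("dropped subject %s: incomplete design", s))
  }
  if (length(keep_subjects) < 2)
    stop("fewer than two subjects with a complete 3 x 2 design")

  get_trial <- function(i) {
    if (inherits(cohort, "gait_cohort")) cohort_trial(cohort, i, emg = config$emg)
    else cohort[[i]]
  }

  metrics <- list(); Eblocks <- list(); vafs <- list(); Ws <- list()
  timing <- list()
  for (s in keep_subjects) {
    rows <- which(trials_meta$subject == s)
    blocks <- list()
    for (i in rows) {
      tr <- get_trial(i)
      res <- run_trial(tr, config)
      metrics[[length(metrics) + 1L]] <- res$metrics
      log <- c(log, res$log)
      if (!is.null(res$E))
        blocks[[paste(tr$meta$time_point, tr$meta$condition, sep = ".")]] <- res$E$E
    }
    if (length(blocks) == 6) {
      fw <- fit_fixed_w(blocks, k = config$k, restarts = config$restarts,
                        max_iter = config$max_iter, tol = config$tol,
                        seed = config$seed)
      if (is.null(W_ref)) W_ref <- fw$W
      perm <- match_synergies(W_ref, fw$W)
      W_aligned <- fw$W[, perm, drop = FALSE]
      Ws[[s]] <- W_aligned
      vafs[[s]] <- fw$vaf
      for (bn in names(fw$A)) {
        tp <- sub("\\..*$", "", bn); cond <- sub("^.*\\.", "", bn)
        A <- fw$A[[bn]][perm, , drop = FALSE]
        for (j in seq_len(config$k)) {
          fw_j <- synergy_fwhm(A[j, ], config$samples_per_stride)
          coa_j <- synergy_coa(A[j, ], config$samples_per_stride)
          timing[[length(timing) + 1L]] <- data.frame(
            subject = s, time_point = tp, condition = cond, synergy = j,
            fwhm = attr(fw_j, "mean"), coa = attr(coa_j, "mean"))
        }
      }
    }
  }
  metrics <- rbind_fill(metrics)
  timing <- if (length(timing)) do.call(rbind, timing) else NULL

  ## long tidy metrics table
  idcols <- c("subject", "time_point", "condition")
  long <- stats::reshape(metrics, direction = "long",
                         varying = setdiff(names(metrics), idcols),
                         v.names = "value", timevar = "metric",
                         times = setdiff(names(metrics), idcols))
  rownames(long) <- NULL
  long <- long[!is.na(long$value), c(idcols, "metric", "value")]

  ## statistics
  anova <- list(); posthoc <- list(); circ <- list()
  two_way <- intersect(c("step_width_mean", "step_width_sd", "com_disp_mean",
                         "com_disp_sd", "com_vel_mean", "lde"),
                       unique(long$metric))
  for (m in two_way) {
    d <- long[long$metric == m, ]
    an <- rm_anova(d, dv = "value", within = c("time_point", "condition"))
    anova[[m]] <- an
    sig_tr <- an$p[an$effect == "time_point"] < 0.05
    sig_int <- an$p[an$effect == "time_point:condition"] < 0.05
    if (isTRUE(sig_tr) || isTRUE(sig_int)) {
      ph <- lapply(GAITSYN_CONDITIONS, function(cc)
        cbind(condition = cc,
              paired_posthoc(d[d$condition == cc, ], dv = "value",
                             factor = "time_point")))
      posthoc[[m]] <- do.call(rbind, ph)
    }
  }
  for (m in intersect(c("fpe_mean", "pct_in_beam"), unique(long$metric))) {
    d <- long[long$metric == m & long$condition == "narrow", ]
    an <- rm_anova(d, dv = "value", within = "time_point")
    anova[[m]] <- an
    if (an$p[1] < 0.05)
      posthoc[[m]] <- paired_posthoc(d, dv = "value", factor = "time_point")
  }
  if (!is.null(timing)) {
    for (j in sort(unique(timing$synergy))) {
      d <- timing[timing$synergy == j, ]
      anova[[paste0("fwhm_syn", j)]] <-
        rm_anova(d, dv = "fwhm", within = c("time_point", "condition"))
      circ[[paste0("coa_syn", j)]] <-
        circ_anova2(d$coa, d$time_point, d$condition)
    }
  }
  list(metrics = long, timing = timing, anova = anova, posthoc = posthoc,
       circ = circ, W = Ws, vaf = unlist(vafs), W_ref = W_ref, log = log,
       config = config)
}

#' Type-I error of the Training effect on synthetic null cohorts
#'
#' Generates replicate null cohorts (no imposed effects), scores mean step
#' width per trial from the ground-truth foot placements through
#' [step_width()], runs the two-way repeated-measures ANOVA, and reports the
#' rejection rate of the Training main effect at level `alpha`.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_strides strides per trial.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return rejection rate, with the vector of p-values as attribute `"p"`.
#' @export
null_rejection_rate <- function(n_reps = 200, n_subjects = 12,
                                n_strides = 160, alpha = 0.05, seed = 1L) {
  seeds <- derive_seeds(seed, n_reps)
  pvals <- vapply(seq_len(n_reps), function(r) {
    ch <- gen_cohort(n_subjects, effects = NULL, seed = seeds[r],
                     n_strides = n_strides)
    mf <- ch$manifest
    mf$value <- vapply(seq_len(nrow(mf)), function(i)
      unname(step_width(gt_placements(ch$gts[[i]]), n_steps = 2 * n_strides)["mean"]),
      0)
    an <- rm_anova(mf, dv = "value", within = c("time_point", "condition"))
    an$p[an$effect == "time_point"]
  }, 0)
  structure(mean(pvals < alpha), p = pvals)
}
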