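# On-disk layout: one directory per trial holding emg.csv, markers.csv,
# cop.csv and a header.json sidecar with sampling rates, units, the axis
# convention and trial metadata; cohort manifests and ground truth are JSON.
# Time base: seconds from trial start, 0-based sample indexing, half-open
# intervals.

#' Write one trial to a directory
#'
#' @param trial a `gait_trial`.
#' @param dir output directory (created if needed).
#' @param ground_truth also write the generator ground truth sidecar
#'   (`ground_truth.json`) when the trial carries one.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir, ground_truth = TRUE) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(trial$emg))
    data.table::fwrite(data.table::as.data.table(t(unclass(trial$emg))),
                       file.path(dir, "emg.csv"))
  mk <- do.call(cbind, lapply(names(trial$markers), function(nm) {
    m <- trial$markers[[nm]]
    colnames(m) <- paste(nm, c("x", "y", "z"), sep = "_")
    m
  }))
  data.table::fwrite(data.table::as.data.table(mk), file.path(dir, "markers.csv"))
  data.table::fwrite(data.table::data.table(x = trial$cop[, 1], y = trial$cop[, 2]),
                     file.path(dir, "cop.csv"))
  hdr <- list(fs_emg = trial$fs_emg, fs_kin = trial$fs_kin,
              fs_cop = trial$fs_cop,
              units = list(emg = "V", markers = "m", cop = "m"),
              axes = "ML=x, AP=y, vertical=z, right-handed, treadmill frame",
              channels = rownames(trial$emg) %||% character(),
              markers = names(trial$markers),
              beam = trial$beam, meta = trial$meta)
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (ground_truth && !is.null(trial$ground_truth)) {
    gt <- trial$ground_truth
    jsonlite::write_json(
      list(seed = gt$seed, condition = gt$condition, dominant = gt$dominant,
           n_strides = gt$n_strides, hs_dom = gt$hs_dom, hs_nd = gt$hs_nd,
           events = gt$events, W_true = gt$W_true,
           profile_params = gt$profile_params,
           step_width_mean = gt$step_width_mean,
           step_width_sd = gt$step_width_sd, foot_width = gt$foot_width,
           beam_halfwidth = gt$beam_halfwidth,
           divergence_gain = gt$divergence_gain, ds_frac = gt$ds_frac,
           duration = gt$duration),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read one trial from a directory
#'
#' Validates channel names against the canonical 11-muscle set, checks
#' stream durations for consistency, and linearly interpolates marker
#' dropouts up to `max_gap` seconds (longer gaps and excessive missingness
#' are errors). Interpolation events are recorded in attribute `"log"`.
#'
#' @param dir trial directory written by [write_trial()].
#' @param max_gap longest marker gap (s) that may be interpolated.
#' @param max_nan_frac maximum tolerated fraction of missing samples per
#'   marker coordinate.
#' @return a `gait_trial`.
#' @export
read_trial <- function(dir, max_gap = 0.2, max_nan_frac = 0.05) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  log <- character()
  emg <- NULL
  if (file.exists(file.path(dir, "emg.csv"))) {
    em <- data.table::fread(file.path(dir, "emg.csv"))
    if (!identical(names(em), GAITSYN_MUSCLES))
      stop("unknown or missing EMG channel name(s): expected exactly {",
           paste(GAITSYN_MUSCLES, collapse = ","), "}, got {",
           paste(names(em), collapse = ","), "}")
    emg <- t(as.matrix(em))
  }
  mk <- data.table::fread(file.path(dir, "markers.csv"))
  marker_names <- unique(sub("_[xyz]$", "", names(mk)))
  markers <- list()
  for (nm in marker_names) {
    m <- as.matrix(mk[, paste(nm, c("x", "y", "z"), sep = "_"), with = FALSE])
    colnames(m) <- c("x", "y", "z")
    for (j in 1:3) {
      nas <- is.na(m[, j])
      if (!any(nas)) next
      if (mean(nas) > max_nan_frac)
        stop("marker ", nm, " has ", round(100 * mean(nas), 1), "% missing samples")
      filled <- zoo::na.approx(m[, j], maxgap = round(max_gap * hdr$fs_kin),
                               na.rm = FALSE, rule = 2)
      if (any(is.na(filled)))
        stop("marker ", nm, " has a gap longer than ", max_gap, " s")
      m[, j] <- filled
      log <- c(log, sprintf("interpolated %d missing samples in %s[%s]",
                            sum(nas), nm, c("x", "y", "z")[j]))
    }
    markers[[nm]] <- m
  }
  cop <- as.matrix(data.table::fread(file.path(dir, "cop.csv")))
  ## all streams share a start time; durations must agree within one sample
  durs <- c(if (!is.null(emg)) ncol(emg) / hdr$fs_emg,
            nrow(markers[[1]]) / hdr$fs_kin, nrow(cop) / hdr$fs_cop)
  if (diff(range(durs)) > 1 / min(hdr$fs_kin, hdr$fs_cop) + 1e-9)
    stop("stream durations disagree by more than one sample")
  trial <- structure(list(
    emg = emg, fs_emg = hdr$fs_emg %||% NA_real_,
    markers = markers, fs_kin = hdr$fs_kin,
    cop = cop, fs_cop = hdr$fs_cop,
    beam = hdr$beam, meta = hdr$meta, ground_truth = NULL
  ), class = "gait_trial")
  attr(trial, "log") <- log
  trial
}

#' Write tidy results tables
#'
#' Long-format results (`subject`, `time_point`, `condition`, `metric`,
#' `value`) with a deterministic column order; `value` must be numeric.
#'
#' @param tables a data.frame or named list of data.frames.
#' @param out_dir output directory.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (is.data.frame(tables)) tables <- list(results = tables)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if ("value" %in% names(tb) && nrow(tb) && !is.numeric(tb$value))
      stop("column 'value' must be numeric in table ", nm)
    lead <- intersect(c("subject", "time_point", "condition", "metric", "value"),
                      names(tb))
    tb <- tb[, c(lead, setdiff(names(tb), lead)), drop = FALSE]
    f <- file.path(out_dir, paste0(nm, ".csv"))
    data.table::fwrite(tb, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a results table written by [write_results()]
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a cohort to disk
#'
#' Materializes every trial of a synthetic cohort into `dir/<subject>_<time
#' point>_<condition>/` and writes `manifest.json`.
#'
#' @param cohort a [gen_cohort()] object.
#' @param dir output directory.
#' @param emg whether to include the EMG stream.
#' @return manifest data.frame with a `path` column, invisibly.
#' @export
write_cohort <- function(cohort, dir, emg = TRUE) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mf <- cohort$manifest
  mf$path <- file.path(dir, paste(mf$subject, mf$time_point, mf$condition, sep = "_"))
  for (i in seq_len(nrow(mf)))
    write_trial(cohort_trial(cohort, i, emg = emg), mf$path[i])
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a cohort manifest
#' @param dir cohort directory containing `manifest.json`.
#' @return data.frame manifest.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
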