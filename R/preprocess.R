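## Quality control and signal conditioning of HbO recordings.
##
## Stage order is fixed: artifact detection on the raw data, steady-state
## trimming, interpolation across flagged samples, global-component removal
## by spatial PCA, zero-phase band-pass, z-scoring.

#' Running-window artifact detection
#'
#' Screens each channel with non-overlapping windows of `window_s` seconds:
#' the mean and SD are computed within each window and samples falling
#' beyond mean +/- `k` SD are flagged as artifacts. A channel is labeled bad
#' when its flagged fraction over the entire time course exceeds
#' `bad_channel_frac`; the subject is flagged for exclusion when the
#' fraction of bad channels exceeds `bad_subject_frac`.
#'
#' @param rec a [recording()].
#' @param window_s window length in seconds (default 10 s).
#' @param k SD multiplier (default 3).
#' @param stride_s window stride; the default equals `window_s`
#'   (non-overlapping windows).
#' @param bad_channel_frac flagged-sample fraction above which a channel is
#'   bad (default 0.05).
#' @param bad_subject_frac bad-channel fraction above which the subject is
#'   excluded (default 0.30).
#' @return a `qc_report`: list with `artifact_frac` (per channel), `bad`
#'   (logical per channel), `excluded` (flag), `mask` (channel x time).
#' @export
detect_artifacts <- function(rec, window_s = 10, k = 3,
                             stride_s = window_s,
                             bad_channel_frac = 0.05,
                             bad_subject_frac = 0.30) {
  fs <- rec$fs
  n <- ncol(rec$data)
  w <- round(window_s * fs)
  if (w > n) stop("detection window longer than the recording")
  stride <- round(stride_s * fs)
  starts <- seq(1, n, by = stride)
  mask <- matrix(FALSE, nrow(rec$data), n)
  for (c in seq_len(nrow(rec$data))) {
    x <- rec$data[c, ]
    for (st in starts) {
      idx <- st:min(st + w - 1, n)
      if (length(idx) < 2) next
      mu <- mean(x[idx]); s <- sd(x[idx])
      if (s == 0) next
      mask[c, idx] <- mask[c, idx] | abs(x[idx] - mu) > k * s
    }
  }
  frac <- rowMeans(mask)
  bad <- frac > bad_channel_frac
  out <- list(artifact_frac = frac, bad = bad,
              excluded = mean(bad) > bad_subject_frac, mask = mask)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> mean artifact fraction %.2f%%; %d/%d bad channel(s); %s\n",
              100 * mean(x$artifact_frac), sum(x$bad), length(x$bad),
              if (x$excluded) "subject EXCLUDED" else "subject retained"))
  invisible(x)
}

#' Trim to the steady-state period
#'
#' Shortens every phase window by `trim_s` seconds at both ends. Data
#' samples are kept; only the phase markers move, so event onsets must be
#' re-referenced with [trim_events()] by the same amount.
#'
#' @param rec a [recording()].
#' @param trim_s seconds removed at each end of each phase (default 15 s).
#' @return the trimmed [recording()].
#' @export
trim_steady_state <- function(rec, trim_s = 15) {
  for (nm in names(rec$phase_windows)) {
    w <- rec$phase_windows[[nm]]
    if (diff(w) <= 2 * trim_s) {
      stop("phase '", nm, "' is too short to trim ", trim_s, " s per end")
    }
    rec$phase_windows[[nm]] <- c(w[1] + trim_s, w[2] - trim_s)
  }
  rec
}

#' Interpolate across flagged artifact samples
#'
#' Replaces flagged samples by linear interpolation between the surrounding
#' clean samples (constant extrapolation at the edges). This is the
#' package's motion-correction step; the flagging rule, not the correction
#' filter, is what the QC contract specifies.
#'
#' @param rec a [recording()].
#' @param mask channel x time logical artifact mask (e.g. from
#'   [detect_artifacts()]).
#' @return the corrected [recording()].
#' @export
interpolate_artifacts <- function(rec, mask) {
  stopifnot(all(dim(mask) == dim(rec$data)))
  for (c in seq_len(nrow(rec$data))) {
    bad <- mask[c, ]
    if (!any(bad) || all(bad)) next
    x <- rec$data[c, ]
    t <- seq_along(x)
    rec$data[c, ] <- approx(t[!bad], x[!bad], xout = t, rule = 2)$y
  }
  rec
}

#' Remove the global physiological component by spatial PCA
#'
#' Performs a spatial principal component analysis across the good channels
#' and projects out the leading components whose cumulative explained
#' variance first reaches `var_threshold` (default 80%). Bad channels are
#' left untouched. Channel means are removed in the process (the subsequent
#' band-pass removes DC anyway).
#'
#' @param rec a [recording()].
#' @param var_threshold cumulative explained-variance threshold in (0, 1].
#' @param qc optional `qc_report`; its bad channels are excluded from the
#'   decomposition and left unmodified.
#' @return the cleaned [recording()], with attribute `n_components_removed`.
#' @export
remove_global_pca <- function(rec, var_threshold = 0.80, qc = NULL) {
  good <- if (is.null(qc)) rep(TRUE, nrow(rec$data)) else !qc$bad
  if (sum(good) < 2) stop("need at least 2 good channels for spatial PCA")
  x <- t(rec$data[good, , drop = FALSE])        # time x channel
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  evar <- sv$d^2 / sum(sv$d^2)
  if (any(!is.finite(evar))) {
    warning("rank-deficient data; removing available components only")
    evar[!is.finite(evar)] <- 0
  }
  ncomp <- which(cumsum(evar) >= var_threshold - 1e-12)[1]
  if (is.na(ncomp)) ncomp <- length(evar)
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  res <- xc - xc %*% v %*% t(v)
  rec$data[good, ] <- t(res)
  attr(rec, "n_components_removed") <- ncomp
  rec
}

#' Zero-phase band-pass filter
#'
#' Applies a 3rd-order Butterworth band-pass (default 0.01-0.5 Hz) forward
#' and backward (`signal::filtfilt`) to every channel, removing slow drifts
#' (including DC) and high-frequency noise without phase distortion --
#' phase shifts would bias the lag analyses downstream.
#'
#' @param rec a [recording()].
#' @param lo,hi band edges in Hz; requires `0 < lo < hi < fs/2`.
#' @param order filter order.
#' @return the filtered [recording()].
#' @export
bandpass <- function(rec, lo = 0.01, hi = 0.5, order = 3) {
  fs <- rec$fs
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop("invalid band: need 0 < lo < hi < fs/2")
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  for (c in seq_len(nrow(rec$data))) {
    x <- rec$data[c, ]
    # remove DC first: shrinks filtfilt edge transients to numerical noise
    rec$data[c, ] <- signal::filtfilt(bf, x - mean(x))
  }
  rec
}

#' Z-score each channel
#'
#' Standardizes every channel to mean 0 and SD 1 over the retained phase
#' span(s). Constant channels cannot be scaled; they are set to zero and
#' flagged in the `zero_channels` attribute.
#'
#' @param rec a [recording()].
#' @param per_phase if `TRUE` (default) each phase window is standardized
#'   separately; otherwise one standardization spans all phases.
#' @return the standardized [recording()].
#' @export
zscore_recording <- function(rec, per_phase = TRUE) {
  spans <- if (per_phase) {
    lapply(seq_along(rec$phase_windows), function(p) phase_samples(rec, p))
  } else {
    list(sort(unique(unlist(lapply(seq_along(rec$phase_windows),
                                   function(p) phase_samples(rec, p))))))
  }
  zero <- logical(nrow(rec$data))
  for (idx in spans) {
    for (c in seq_len(nrow(rec$data))) {
      x <- rec$data[c, idx]
      s <- sd(x)
      if (!is.finite(s) || s < 1e-12) {
        rec$data[c, idx] <- 0
        zero[c] <- TRUE
      } else {
        rec$data[c, idx] <- (x - mean(x)) / s
      }
    }
  }
  attr(rec, "zero_channels") <- which(zero)
  rec
}

#' Full preprocessing pipeline for one recording
#'
#' Runs the conditioning stages in their fixed order: artifact detection on
#' the raw data, steady-state trimming, artifact interpolation, global
#' component removal by spatial PCA, band-pass filtering, z-scoring. QC
#' decisions therefore depend only on the pre-trim raw data.
#'
#' @param rec a [recording()].
#' @param event_set optional [event_set()]; when supplied its onsets are
#'   re-referenced to the trimmed phase and returned alongside.
#' @param window_s,k artifact-detection parameters (see
#'   [detect_artifacts()]).
#' @param trim_s steady-state trim per phase end.
#' @param var_threshold PCA explained-variance threshold.
#' @param lo,hi band-pass edges in Hz.
#' @param per_phase z-scoring span (see [zscore_recording()]).
#' @return list with `recording` (processed, with `$qc` set), `qc` and, if
#'   supplied, the re-referenced `event_set`.
#' @export
preprocess <- function(rec, event_set = NULL, window_s = 10, k = 3,
                       trim_s = 15, var_threshold = 0.80, lo = 0.01,
                       hi = 0.5, per_phase = TRUE) {
  qc <- detect_artifacts(rec, window_s = window_s, k = k)
  rec <- trim_steady_state(rec, trim_s = trim_s)
  rec <- interpolate_artifacts(rec, qc$mask)
  rec <- remove_global_pca(rec, var_threshold = var_threshold, qc = qc)
  rec <- bandpass(rec, lo = lo, hi = hi)
  rec <- zscore_recording(rec, per_phase = per_phase)
  rec$qc <- qc
  out <- list(recording = rec, qc = qc)
  if (!is.null(event_set)) out$event_set <- trim_events(event_set, trim_s)
  out
}

#' Preprocess a whole cohort
#'
#' Applies [preprocess()] to every student (and the teacher, if present) of
#' a cohort from [simulate_cohort()] or assembled by hand, re-references the
#' shared event set once, and drops students whose QC report flags them for
#' exclusion.
#'
#' @param cohort list with `students` (list of recordings), optional
#'   `teacher`, and `event_set`.
#' @param ... passed on to [preprocess()].
#' @return the cohort with processed recordings, re-referenced `event_set`,
#'   per-subject `qc` list and `excluded` (subject ids dropped).
#' @export
preprocess_cohort <- function(cohort, ...) {
  args <- list(...)
  trim_s <- args$trim_s %||% 15
  run <- function(r) do.call(preprocess, c(list(r), args))
  st <- lapply(cohort$students, run)
  excluded <- vapply(st, function(s) s$qc$excluded, logical(1))
  cohort$qc <- lapply(st, `[[`, "qc")
  cohort$excluded <- vapply(cohort$students[excluded], `[[`,
                            character(1), "subject_id")
  cohort$students <- lapply(st[!excluded], `[[`, "recording")
  if (!is.null(cohort$teacher)) {
    cohort$teacher <- run(cohort$teacher)$recording
  }
  cohort$event_set <- trim_events(cohort$event_set, trim_s)
  cohort
}
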