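#' Multichannel hemodynamic recordings
#'
#' A `recording` is one participant's channel-by-time oxygenated-hemoglobin
#' (HbO) matrix at a fixed sampling rate, together with the participant's
#' role, per-channel labels, named phase windows and (after quality control)
#' a QC report. Event onsets are interpreted relative to the start of a
#' phase window; sample indexing is 0-based in time, so the sample covering
#' time `t` seconds is `floor(t * fs) + 1` in R's 1-based matrices.
#'
#' @param data numeric channel x time matrix (HbO; arbitrary concentration
#'   units before z-scoring, z-units after).
#' @param fs sampling rate in Hz.
#' @param subject_id participant identifier.
#' @param role `"student"` or `"teacher"`.
#' @param channel_labels character vector, one per channel.
#' @param phase_windows named list of `c(start_s, end_s)` spans; defaults to
#'   one `main` phase covering the whole recording.
#' @return an object of class `recording`.
#' @export
recording <- function(data, fs, subject_id = "S1",
                      role = c("student", "teacher"),
                      channel_labels = NULL, phase_windows = NULL) {
  role <- match.arg(role)
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  C <- nrow(data)
  channel_labels <- channel_labels %||% paste0("CH", seq_len(C))
  stopifnot(length(channel_labels) == C)
  dur <- ncol(data) / fs
  phase_windows <- phase_windows %||% list(main = c(0, dur))
  for (w in phase_windows) {
    if (length(w) != 2 || w[1] < -1e-9 || w[2] > dur + 1e-9 || w[2] <= w[1]) {
      stop("phase windows must be increasing spans inside the recording")
    }
  }
  structure(list(subject_id = subject_id, role = role, data = data, fs = fs,
                 channel_labels = channel_labels,
                 phase_windows = phase_windows, qc = NULL),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$role, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  for (nm in names(x$phase_windows)) {
    w <- x$phase_windows[[nm]]
    cat(sprintf("  phase %-10s %.1f-%.1f s\n", nm, w[1], w[2]))
  }
  if (!is.null(x$qc)) {
    cat(sprintf("  QC: %d bad channel(s)%s\n", sum(x$qc$bad),
                if (isTRUE(x$qc$excluded)) ", subject excluded" else ""))
  }
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)

# sample indices (1-based) of a phase window
phase_samples <- function(rec, phase = 1) {
  w <- rec$phase_windows[[phase]]
  if (is.null(w)) stop("unknown phase window")
  (floor(w[1] * rec$fs) + 1):floor(w[2] * rec$fs)
}

#' Write a recording as a plain-text archive
#'
#' The archive is a documented two-file container: `<prefix>.tsv` holds the
#' time x channel data matrix with channel labels as header, and
#' `<prefix>.json` holds the metadata block (`subject_id`, `role`, `fs`,
#' `channel_labels`, `phase_windows`).
#'
#' @param rec a [recording()].
#' @param prefix output path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  dat <- as.data.frame(t(rec$data))
  names(dat) <- rec$channel_labels
  write.table(format(dat, digits = 10, trim = TRUE, scientific = FALSE),
              paste0(prefix, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, role = rec$role, fs = rec$fs,
               channel_labels = rec$channel_labels,
               phase_windows = rec$phase_windows)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording from a plain-text archive
#'
#' Counterpart of [write_recording()]. Fails with a descriptive error when
#' the metadata block is missing or incomplete.
#'
#' @param prefix path prefix of the archive (expects `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @return a [recording()].
#' @export
read_recording <- function(prefix) {
  data_path <- paste0(prefix, ".tsv")
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(data_path)) stop("missing recording data file: ", data_path)
  if (!file.exists(meta_path)) stop("missing recording metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("subject_id", "role", "fs", "channel_labels")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("recording metadata lacks field(s): ", paste(miss, collapse = ", "))
  }
  dat <- read.delim(data_path, sep = "\t", check.names = FALSE)
  pw <- lapply(meta$phase_windows, as.numeric)
  recording(t(as.matrix(dat)), fs = meta$fs, subject_id = meta$subject_id,
            role = meta$role, channel_labels = meta$channel_labels,
            phase_windows = if (length(pw)) pw else NULL)
}
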