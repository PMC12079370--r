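#' Knowledge event sets
#'
#' An `event_set` holds the ordered, non-overlapping knowledge events of one
#' teaching phase: onset, duration and identifier per event, plus (optionally)
#' the per-event semantic topic vectors used to build the knowledge matrix and
#' the shared topic-basis waveforms used by the synthetic generator. Onsets
#' are in seconds relative to the start of the recording's phase window;
#' event intervals are half-open `[onset, offset)`.
#'
#' @param onset_s numeric vector of event onsets (seconds).
#' @param duration_s numeric vector of event durations (seconds).
#' @param event_id optional event identifiers (default `E1..EM`).
#' @param topics optional M x K matrix of non-negative topic weights, one row
#'   per event.
#' @param phase phase label, e.g. `"lecturing"` or `"recalling"`.
#' @param basis optional Lmax x K matrix of topic-basis waveforms (used by
#'   [simulate_recording()]).
#' @param fs sampling rate (Hz) at which `basis` is sampled.
#' @return an object of class `event_set`.
#' @export
event_set <- function(onset_s, duration_s, event_id = NULL, topics = NULL,
                      phase = "lecturing", basis = NULL, fs = 10) {
  stopifnot(length(onset_s) == length(duration_s))
  m <- length(onset_s)
  if (m < 1) stop("event set must contain at least one event")
  if (any(!is.finite(onset_s)) || any(!is.finite(duration_s))) {
    stop("event onsets and durations must be finite")
  }
  if (any(duration_s <= 0)) {
    stop("invalid event configuration: non-positive durations in rows ",
         paste(which(duration_s <= 0), collapse = ", "))
  }
  ord <- order(onset_s)
  onset_s <- onset_s[ord]
  duration_s <- duration_s[ord]
  event_id <- (event_id %||% paste0("E", seq_len(m)))[ord]
  offset_s <- onset_s + duration_s
  if (m > 1 && any(offset_s[-m] > onset_s[-1] + 1e-9)) {
    bad <- which(offset_s[-m] > onset_s[-1] + 1e-9)
    stop("overlapping events in rows ", paste(bad, collapse = ", "))
  }
  if (!is.null(topics)) {
    topics <- as.matrix(topics)
    if (nrow(topics) != m) stop("topics must have one row per event")
    if (any(!is.finite(topics)) || any(topics < 0)) {
      stop("topic vectors must be finite and non-negative")
    }
    zero <- rowSums(topics) == 0
    if (any(zero)) {
      stop("all-zero topic vector for event ",
           paste(event_id[zero], collapse = ", "))
    }
    topics <- topics[ord, , drop = FALSE]
    rownames(topics) <- event_id
  }
  structure(list(
    events = data.frame(event_id = event_id, onset_s = onset_s,
                        duration_s = duration_s, offset_s = offset_s,
                        stringsAsFactors = FALSE),
    topics = topics, phase = phase, basis = basis, fs = fs
  ), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  m <- nrow(x$events)
  cat(sprintf("<event_set> %d events, phase '%s'\n", m, x$phase))
  cat(sprintf("  span: %.1f-%.1f s, durations %.1f-%.1f s (mean %.1f)\n",
              min(x$events$onset_s), max(x$events$offset_s),
              min(x$events$duration_s), max(x$events$duration_s),
              mean(x$events$duration_s)))
  if (!is.null(x$topics)) {
    cat(sprintf("  topic vectors: K = %d\n", ncol(x$topics)))
  }
  invisible(x)
}

n_events <- function(es) nrow(es$events)

#' Re-reference event onsets after steady-state trimming
#'
#' Shifts all onsets by `-trim_s`, matching a phase window whose start moved
#' forward by `trim_s` seconds (see [trim_steady_state()]).
#'
#' @param event_set an [event_set()].
#' @param trim_s seconds removed from the start of the phase window.
#' @return the re-referenced `event_set`.
#' @export
trim_events <- function(event_set, trim_s = 15) {
  es <- event_set
  new_onset <- es$events$onset_s - trim_s
  if (any(new_onset < -1e-9)) {
    stop("trimming by ", trim_s, " s would move events before the phase start")
  }
  es$events$onset_s <- new_onset
  es$events$offset_s <- es$events$offset_s - trim_s
  es
}

#' Read a knowledge event table
#'
#' Reads a tab-separated event table with columns `onset_s`, `duration_s`,
#' `event_id` and, optionally, a parallel tab-separated topic-vector file
#' (one row per event). Rows violating the event-set invariants are reported
#' by row number.
#'
#' @param path path to the event TSV.
#' @param topics_path optional path to a topic-weight TSV.
#' @param phase phase label to attach.
#' @return an [event_set()].
#' @export
read_events <- function(path, topics_path = NULL, phase = "lecturing") {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "event_id")
  if (!all(need %in% names(tab))) {
    stop("event table must have columns ", paste(need, collapse = ", "))
  }
  topics <- if (!is.null(topics_path)) {
    as.matrix(read.delim(topics_path, sep = "\t"))
  }
  event_set(tab$onset_s, tab$duration_s, tab$event_id, topics = topics,
            phase = phase)
}

#' Write a knowledge event table
#'
#' @param event_set an [event_set()].
#' @param path output TSV path (columns `onset_s`, `duration_s`, `event_id`).
#' @param topics_path optional output path for the topic-weight TSV.
#' @return `path`, invisibly.
#' @export
write_events <- function(event_set, path, topics_path = NULL) {
  ev <- event_set$events[, c("onset_s", "duration_s", "event_id")]
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(topics_path)) {
    if (is.null(event_set$topics)) stop("event set carries no topic vectors")
    write.table(event_set$topics, topics_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
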