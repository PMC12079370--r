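## Event-boundary contrast: post-offset vs mid-event activity.

#' Boundary vs non-boundary activity for one subject
#'
#' After shifting the signal forward by `hrf_shift_s` seconds to account for
#' the hemodynamic delay, the boundary pattern is the mean z-scored activity
#' over the first `window_s` seconds following each event offset, and the
#' non-boundary pattern is the mean over the middle `window_s` seconds of
#' each event. Events shorter than `window_s` are excluded from the
#' non-boundary average only; boundary windows always exist post-offset but
#' are dropped when they overrun the phase end. Boundary windows may slide
#' into the following event's span.
#'
#' @param rec a preprocessed [recording()] (z-units).
#' @param event_set an [event_set()].
#' @param channel channel index.
#' @param window_s window length in seconds (15 for lecturing, 6 for the
#'   shorter recalled events).
#' @param hrf_shift_s hemodynamic delay compensation in seconds.
#' @param phase phase window.
#' @return list with `boundary`, `non_boundary`, `difference` (z-units) and
#'   the event counts entering each average.
#' @export
boundary_effect <- function(rec, event_set, channel, window_s = 15,
                            hrf_shift_s = 6, phase = 1) {
  xs <- channel_series(rec, channel, phase)
  fs <- rec$fs
  w <- round(window_s * fs)
  shift <- round(hrf_shift_s * fs)
  ev <- event_set$events
  win_mean <- function(start_s) {
    i0 <- round(start_s * fs) + shift
    if (i0 < 0 || i0 + w > length(xs)) return(NA_real_)
    mean(xs[i0 + seq_len(w)])
  }
  bnd <- vapply(ev$offset_s, win_mean, numeric(1))
  eligible <- ev$duration_s >= window_s
  nb <- vapply(which(eligible), function(m) {
    mid <- (ev$onset_s[m] + ev$offset_s[m]) / 2
    win_mean(mid - window_s / 2)
  }, numeric(1))
  bnd <- bnd[is.finite(bnd)]
  nb <- nb[is.finite(nb)]
  if (!length(bnd) || !length(nb)) {
    stop("no eligible events for the boundary contrast")
  }
  list(boundary = mean(bnd), non_boundary = mean(nb),
       difference = mean(bnd) - mean(nb),
       n_boundary_events = length(bnd), n_nonboundary_events = length(nb))
}

#' Group test on per-subject boundary differences
#'
#' Paired test of boundary vs non-boundary means, computed as a one-sample
#' t-test on the per-subject differences, with Cohen's d and the 95%
#' confidence interval of the difference. Zero-variance inputs are flagged
#' as degenerate (all-zero differences give t = 0, p = 1).
#'
#' @param differences numeric vector of per-subject boundary minus
#'   non-boundary means (>= 3 subjects).
#' @return list with `t`, `df`, `p`, `d`, `ci`, `n`, `mean`, `degenerate`.
#' @export
group_boundary_test <- function(differences) {
  one_sample_stats(differences)
}

#' Boundary-effect analysis across a cohort
#'
#' Computes [boundary_effect()] for every student and runs the paired group
#' test on the differences.
#'
#' @param x a cohort list or list of student [recording()]s.
#' @param event_set an [event_set()]; defaults to `x$event_set`.
#' @param channel channel index.
#' @param window_s,hrf_shift_s,phase see [boundary_effect()].
#' @return an object of class `boundary_test` with the per-subject table and
#'   the group statistics.
#' @export
boundary_test <- function(x, event_set = NULL, channel, window_s = 15,
                          hrf_shift_s = 6, phase = 1) {
  recs <- if (!is.null(x$students)) x$students else x
  event_set <- event_set %||% x$event_set
  per <- lapply(recs, boundary_effect, event_set, channel,
                window_s = window_s, hrf_shift_s = hrf_shift_s,
                phase = phase)
  tab <- data.frame(
    subject = vapply(recs, `[[`, character(1), "subject_id"),
    boundary = vapply(per, `[[`, numeric(1), "boundary"),
    non_boundary = vapply(per, `[[`, numeric(1), "non_boundary"),
    difference = vapply(per, `[[`, numeric(1), "difference"),
    stringsAsFactors = FALSE)
  structure(list(table = tab, group = group_boundary_test(tab$difference),
                 channel = channel, window_s = window_s,
                 hrf_shift_s = hrf_shift_s),
            class = "boundary_test")
}

#' @export
print.boundary_test <- function(x, ...) {
  g <- x$group
  cat(sprintf("Boundary contrast on channel %s (window %g s, HRF shift %g s)\n",
              x$channel, x$window_s, x$hrf_shift_s))
  cat(sprintf("  boundary %.3f vs non-boundary %.3f (z units), n = %d\n",
              mean(x$table$boundary), mean(x$table$non_boundary), g$n))
  if (isTRUE(g$degenerate)) cat("  degenerate: zero-variance differences\n")
  cat(sprintf("  paired t(%d) = %.3f, p = %.4g, Cohen's d = %.3f, 95%% CI [%.3f, %.3f]\n",
              g$df, g$t, g$p, g$d, g$ci[1], g$ci[2]))
  invisible(x)
}

#' Write per-subject boundary results
#'
#' @param x a [boundary_test()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_boundary_table <- function(x, path) {
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
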