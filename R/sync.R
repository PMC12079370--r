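## Time-lagged teacher-student representational synchronization.

#' Lagged teacher brain matrix
#'
#' Shifts the teacher's channel series by `lag_s` seconds (positive lag =
#' teacher precedes the students, so the teacher's series is read `lag_s`
#' seconds earlier than each event window) and builds the teacher's
#' event-by-event matrix with the same inter-subject correlation machinery:
#' the teacher's shifted events are correlated with each student's events
#' and the symmetrized pair matrices are averaged over students. Events
#' whose shifted window leaves the recorded span are dropped and masked.
#' A teacher-autocorrelation variant (`against = "teacher"`) is available
#' but is not the default, since within-subject autocorrelation aliases
#' into the event similarities.
#'
#' @param teacher the teacher's [recording()].
#' @param students list of student [recording()]s.
#' @param event_set an [event_set()].
#' @param t_channel teacher channel index.
#' @param s_channel student channel index (defaults to `t_channel`).
#' @param lag_s lag in seconds (positive = teacher precedes).
#' @param against `"students"` (default) or `"teacher"`.
#' @param phase phase window.
#' @return a [sim_matrix()] of kind `"brain"`; attribute `dropped_events`
#'   lists events truncated away by the shift.
#' @export
lagged_teacher_matrix <- function(teacher, students, event_set, t_channel,
                                  s_channel = t_channel, lag_s = 0,
                                  against = c("students", "teacher"),
                                  phase = 1) {
  against <- match.arg(against)
  fs <- teacher$fs
  lag_samples <- round(lag_s * fs)
  bt <- event_block(channel_series(teacher, t_channel, phase), event_set,
                    fs, lag_samples = lag_samples)
  vals <- if (against == "teacher") {
    C <- cpp_pair_corr(bt$E, bt$E, bt$lens)
    (C + t(C)) / 2
  } else {
    cc <- cohort_cube(lapply(students, channel_series, s_channel, phase),
                      event_set, fs)
    cpp_mean_pair_with(bt$E, cc$cube, cc$lens)
  }
  mask <- is.finite(vals)
  diag(mask) <- FALSE
  mask[bt$dropped, ] <- FALSE
  mask[, bt$dropped] <- FALSE
  vals[!mask] <- NA_real_
  out <- sim_matrix(vals, mask, kind = "brain")
  attr(out, "dropped_events") <- which(bt$dropped)
  out
}

#' Time-lagged teacher-student synchronization scan
#'
#' For every (teacher channel, student channel, lag) grid cell, computes
#' the Spearman correlation between the teacher's lagged brain matrix and
#' the student cohort's mean brain matrix at that student channel. The lag
#' grid defaults to -14..-6 and +6..+14 s in 2 s steps (positive lag =
#' teacher precedes). Optional permutation inference surrogate-transforms
#' every student's series per iteration, recomputes the full grid, and
#' applies Benjamini-Hochberg FDR across all grid cells.
#'
#' @param teacher the teacher's [recording()].
#' @param x a cohort list or list of student [recording()]s.
#' @param event_set an [event_set()]; defaults to `x$event_set`.
#' @param t_channels,s_channels channel index vectors for the two sides
#'   (default: all channels).
#' @param lags_s lag grid in seconds.
#' @param n_perm permutation iterations (0 skips inference).
#' @param method surrogate type (see [surrogate_series()]).
#' @param q FDR threshold across the whole grid.
#' @param shift which party's series is shifted (`"teacher"` default;
#'   `"students"` negates the recovered lag by construction).
#' @param seed integer seed.
#' @param phase phase window.
#' @return an object of class `sync_scan` with the long-format grid table
#'   (`t_channel`, `s_channel`, `lag_s`, `r`, `p`, `q_value`,
#'   `significant`).
#' @export
sync_scan <- function(teacher, x, event_set = NULL, t_channels = NULL,
                      s_channels = NULL,
                      lags_s = c(-seq(14, 6, by = -2), seq(6, 14, by = 2)),
                      n_perm = 0,
                      method = c("phase_randomize", "time_shuffle",
                                 "circular_shift"),
                      q = 0.05, shift = c("teacher", "students"),
                      seed = NULL, phase = 1) {
  method <- match.arg(method)
  shift <- match.arg(shift)
  students <- if (!is.null(x$students)) x$students else x
  event_set <- event_set %||% x$event_set
  if (length(students) < 2) stop("need a teacher plus at least 2 students")
  fs <- teacher$fs
  t_channels <- t_channels %||% seq_len(n_channels(teacher))
  s_channels <- s_channels %||% seq_len(n_channels(students[[1]]))
  grid_r <- function(t_xs_by_ch, s_xs_by_ch) {
    # teacher blocks per (channel, lag); student cubes per channel
    out <- numeric(length(t_channels) * length(s_channels) * length(lags_s))
    i <- 0L
    for (sc in seq_along(s_channels)) {
      cc <- cohort_cube(s_xs_by_ch[[sc]], event_set, fs)
      smean <- cpp_mean_cohort_mat(cc$cube, cc$lens)
      smask <- is.finite(smean)
      diag(smask) <- FALSE
      s_sim <- sim_matrix(replace(smean, !smask, NA_real_), smask, "brain")
      for (tc in seq_along(t_channels)) {
        for (lg in seq_along(lags_s)) {
          lag <- lags_s[lg]
          tl <- if (shift == "teacher") lag else 0
          sl <- if (shift == "students") lag else 0
          bt <- event_block(t_xs_by_ch[[tc]], event_set, fs,
                            lag_samples = round(tl * fs))
          scube <- if (sl == 0) cc else {
            cohort_cube(lapply(s_xs_by_ch[[sc]], shift_series,
                               round(sl * fs)), event_set, fs)
          }
          tmat <- cpp_mean_pair_with(bt$E, scube$cube, scube$lens)
          tmask <- is.finite(tmat)
          diag(tmask) <- FALSE
          tmask[bt$dropped, ] <- FALSE
          tmask[, bt$dropped] <- FALSE
          t_sim <- sim_matrix(replace(tmat, !tmask, NA_real_), tmask,
                              "brain")
          i <- i + 1L
          out[i] <- rsa_correlation(t_sim, s_sim)
        }
      }
    }
    out
  }
  t_xs <- lapply(t_channels, function(ch) channel_series(teacher, ch, phase))
  s_xs <- lapply(s_channels, function(ch) {
    lapply(students, channel_series, ch, phase)
  })
  r <- grid_r(t_xs, s_xs)
  p <- rep(NA_real_, length(r))
  if (n_perm > 0) {
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        s_surr <- lapply(s_xs, function(per_ch) {
          lapply(per_ch, surrogate_series, method = method)
        })
        grid_r(t_xs, s_surr)
      }, numeric(length(r)))
    })
    if (is.null(dim(null))) null <- matrix(null, nrow = 1)
    p <- vapply(seq_along(r), function(i) {
      permutation_pvalue(r[i], null[i, ])
    }, numeric(1))
  }
  fdr <- if (n_perm > 0) fdr_correct(p, q) else
    list(q_values = rep(NA_real_, length(p)),
         significant = rep(NA, length(p)))
  # expansion order must match the loops above: s_channel outer, then
  # t_channel, then lag
  tab <- data.frame(
    s_channel = rep(s_channels, each = length(t_channels) * length(lags_s)),
    t_channel = rep(rep(t_channels, each = length(lags_s)),
                    times = length(s_channels)),
    lag_s = rep(lags_s, times = length(s_channels) * length(t_channels)),
    r = r, p = p, q_value = fdr$q_values, significant = fdr$significant)
  tab <- tab[, c("t_channel", "s_channel", "lag_s", "r", "p", "q_value",
                 "significant")]
  structure(list(table = tab, lags_s = lags_s, n_perm = n_perm,
                 method = method, q = q, shift = shift,
                 n_students = length(students)),
            class = "sync_scan")
}

# plain sample shift used when the student side is the shifted party;
# positive k reads earlier samples (content moves later)
shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  out <- numeric(n)
  if (k > 0) {
    out[(k + 1):n] <- x[1:(n - k)]
  } else {
    out[1:(n + k)] <- x[(-k + 1):n]
  }
  out
}

#' Peak of a synchronization scan
#'
#' @param x a [sync_scan()] result.
#' @return one-row data frame with the grid cell of maximal r.
#' @export
sync_peak <- function(x) {
  tab <- x$table[is.finite(x$table$r), , drop = FALSE]
  tab[which.max(tab$r), , drop = FALSE]
}

#' @export
print.sync_scan <- function(x, ...) {
  cat(sprintf("Teacher-student synchronization scan: %d x %d channel pairs, lags {%s} s\n",
              length(unique(x$table$t_channel)),
              length(unique(x$table$s_channel)),
              paste(x$lags_s, collapse = ", ")))
  pk <- sync_peak(x)
  cat(sprintf("  peak r = %.3f at teacher CH%d -> student CH%d, lag %+g s\n",
              pk$r, pk$t_channel, pk$s_channel, pk$lag_s))
  if (x$n_perm > 0) {
    cat(sprintf("  permutation null (%s, %d iter), BH-FDR: %d significant cell(s) at q < %.2f\n",
                x$method, x$n_perm, sum(x$table$significant, na.rm = TRUE),
                x$q))
  }
  invisible(x)
}

#' @export
summary.sync_scan <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' @export
plot.sync_scan <- function(x, t_channel = NULL, s_channel = NULL, ...) {
  tab <- x$table
  pk <- sync_peak(x)
  t_channel <- t_channel %||% pk$t_channel
  s_channel <- s_channel %||% pk$s_channel
  sel <- tab[tab$t_channel == t_channel & tab$s_channel == s_channel, ]
  sel <- sel[order(sel$lag_s), ]
  graphics::plot(sel$lag_s, sel$r, type = "b", pch = 16,
                 xlab = "lag (s, positive = teacher precedes)",
                 ylab = "Spearman r",
                 main = sprintf("teacher CH%d vs student CH%d",
                                t_channel, s_channel), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Write a synchronization grid as long-format TSV
#'
#' @param x a [sync_scan()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sync_table <- function(x, path) {
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
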