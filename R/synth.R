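## Synthetic classroom cohorts with known ground truth.
##
## The generator emulates the statistical structure the downstream analyses
## assume: event-locked signals whose inter-subject event-pair correlations
## track a known knowledge similarity matrix, offset-locked hemodynamic
## boundary transients, autocorrelated channel noise plus a per-subject
## global physiological component, motion spikes, and a teacher whose
## embedded signal leads the students by a fixed number of seconds.

#' Configuration of the synthetic cohort generator
#'
#' Collects the generator's knobs in one validated list. Defaults describe a
#' single-lesson classroom cohort: 12 students, 22 measurement channels,
#' 26 knowledge events at a 10 Hz sampling rate, event durations between 6
#' and 200 s with a long-tailed distribution whose mean is close to 52.7 s.
#'
#' @param n_students number of student recordings.
#' @param n_channels channels per recording.
#' @param n_events number of knowledge events (M).
#' @param n_topics topic-vector dimensionality (K).
#' @param fs sampling rate in Hz.
#' @param duration_range `c(min, max)` event duration bounds in seconds
#'   (minimum at least 6 s).
#' @param mean_duration_s optional target mean event duration; the default
#'   `NULL` uses a truncated-exponential scale that reproduces a 52.7 s mean
#'   under the default `(6, 200)` s range.
#' @param concentration symmetric Dirichlet concentration of the per-event
#'   topic vectors; `Inf` makes all vectors identical.
#' @param embed_channel channel index carrying the knowledge-locked signal.
#' @param embed_strength shared-signal variance fraction rho in `[0, 1]` on
#'   the embedded channel.
#' @param boundary_amp amplitude (z units) of the offset-locked hemodynamic
#'   transient added on the embedded channel.
#' @param boundary_at where the transient is anchored: event `"offset"`
#'   (the boundary response) or `"midpoint"` (a reversed-effect control).
#' @param teacher_lead seconds by which the teacher's embedded signal leads
#'   the students'.
#' @param noise_ar AR(1) coefficient of the channel noise, in `[0, 1)`.
#' @param global_amp amplitude of the per-subject global physiological
#'   component (added to every channel with a random gain in `[0.5, 1.5]`).
#' @param subject_distortion non-negative scalar; per-student Dirichlet
#'   resampling of the embedded topic weights (0 = all students embed the
#'   identical event signal, larger values = more idiosyncratic structure).
#' @param seed integer seed for the whole cohort.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_students = 12, n_channels = 22, n_events = 26,
                         n_topics = 12, fs = 10, duration_range = c(6, 200),
                         mean_duration_s = NULL, concentration = 0.4,
                         embed_channel = 3, embed_strength = 0.5,
                         boundary_amp = 0.5,
                         boundary_at = c("offset", "midpoint"),
                         teacher_lead = 8, noise_ar = 0.3, global_amp = 1,
                         subject_distortion = 0, seed = 1L) {
  boundary_at <- match.arg(boundary_at)
  cfg <- list(n_students = n_students, n_channels = n_channels,
              n_events = n_events, n_topics = n_topics, fs = fs,
              duration_range = duration_range,
              mean_duration_s = mean_duration_s,
              concentration = concentration, embed_channel = embed_channel,
              embed_strength = embed_strength, boundary_amp = boundary_amp,
              boundary_at = boundary_at, teacher_lead = teacher_lead,
              noise_ar = noise_ar, global_amp = global_amp,
              subject_distortion = subject_distortion, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$n_students >= 1, cfg$n_channels >= 1,
            cfg$n_events >= 3, cfg$n_topics >= 2)
  if (length(cfg$duration_range) != 2 || cfg$duration_range[1] < 6 ||
      diff(cfg$duration_range) < 0) {
    stop("invalid config: duration_range must be c(min, max) with min >= 6 s")
  }
  if (cfg$embed_strength < 0 || cfg$embed_strength > 1) {
    stop("invalid config: embed_strength (rho) must lie in [0, 1]")
  }
  if (cfg$noise_ar < 0 || cfg$noise_ar >= 1) {
    stop("invalid config: noise_ar must lie in [0, 1)")
  }
  if (cfg$embed_channel < 1 || cfg$embed_channel > cfg$n_channels) {
    stop("invalid config: embed_channel outside 1..n_channels")
  }
  if (cfg$teacher_lead < 0) stop("invalid config: teacher_lead must be >= 0")
  if (cfg$subject_distortion < 0) {
    stop("invalid config: subject_distortion must be >= 0")
  }
  invisible(cfg)
}

# Dirichlet draws composed from gamma variates
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  s <- rowSums(g)
  if (any(s == 0)) {
    # all-zero draw is possible for tiny alpha; fall back to one-hot
    for (i in which(s == 0)) g[i, sample.int(k, 1)] <- 1
    s <- rowSums(g)
  }
  g / s
}

# canonical double-gamma hemodynamic response, peak at 6 s, peak height 1
hrf_kernel <- function(fs, length_s = 30) {
  t <- seq(0, length_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# boundary response: a short neural burst (boxcar) convolved with the
# canonical HRF, peak-normalized; an extended response is what a 15 s
# post-offset window is meant to capture
boundary_kernel <- function(fs, burst_s = 6) {
  h <- hrf_kernel(fs)
  box <- rep(1, round(burst_s * fs))
  k <- convolve(c(h, numeric(length(box))), rev(box), type = "open")
  k <- k[seq_len(length(h) + length(box))] / fs
  k / max(k)
}

# K smooth orthonormalized topic-basis waveforms (unit SD columns);
# low-pass filtered white noise so the structure survives the analysis
# band-pass
smooth_basis <- function(n_samples, k, fs, cutoff = 0.2) {
  raw <- matrix(rnorm(n_samples * k), n_samples, k)
  bf <- signal::butter(3, min(cutoff / (fs / 2), 0.99), type = "low")
  sm <- apply(raw, 2, function(col) signal::filtfilt(bf, col))
  sm <- scale(sm, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(sm))
  q * sqrt(n_samples - 1)
}

ar1_series <- function(n, ar) {
  if (ar == 0) return(rnorm(n))
  as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - ar^2)), ar,
                           method = "recursive"))
}

# truncated-exponential duration scale; default reproduces a 52.7 s mean
# under the (6, 200) s range
duration_scale <- function(range, target_mean = NULL) {
  lo <- range[1]; hi <- range[2]
  if (hi == lo) return(0)
  if (is.null(target_mean)) return(0.2451 * (hi - lo))
  if (target_mean <= lo || target_mean >= hi) {
    stop("mean_duration_s must lie strictly inside duration_range")
  }
  f <- function(s) lo + s * (1 - exp(-(hi - lo) / s)) - target_mean
  stats::uniroot(f, c(1e-3, 100 * (hi - lo)))$root
}

#' Generate a synthetic knowledge event set
#'
#' Draws ordered, non-overlapping events tiling a session (after a 20 s
#' lead-in), with durations from a truncated shifted-exponential inside
#' `duration_range`, per-event topic vectors from a symmetric Dirichlet, and
#' the shared smooth topic-basis waveforms used to embed event signals into
#' recordings. The knowledge matrix follows via [cosine_knowledge_matrix()].
#'
#' @param n_events number of events (at least 3).
#' @param n_topics topic dimensionality K.
#' @param duration_range `c(min, max)` duration bounds (min at least 6 s).
#' @param concentration symmetric Dirichlet concentration (`Inf` = identical
#'   vectors).
#' @param seed integer seed.
#' @param fs sampling rate the basis is sampled at.
#' @param mean_duration_s optional target mean duration (see
#'   [synth_config()]).
#' @param start_s onset of the first event within the phase window.
#' @param phase phase label.
#' @return an [event_set()] with `topics` and `basis` attached.
#' @export
make_event_set <- function(n_events, n_topics, duration_range = c(6, 200),
                           concentration = 0.4, seed = NULL, fs = 10,
                           mean_duration_s = NULL, start_s = 20,
                           phase = "lecturing") {
  if (n_events < 3) stop("invalid config: need at least 3 events")
  if (duration_range[1] <= 0) {
    stop("invalid config: non-positive durations")
  }
  if (duration_range[1] < 6) {
    stop("invalid config: duration_range minimum must be >= 6 s")
  }
  with_seed(seed, {
    lo <- duration_range[1]; hi <- duration_range[2]
    sc <- duration_scale(duration_range, mean_duration_s)
    d <- if (sc == 0) rep(lo, n_events) else
      lo + pmin(rexp(n_events, rate = 1 / sc), hi - lo)
    d <- round(d * fs) / fs          # whole samples
    d <- pmin(pmax(d, lo), hi)
    onset <- start_s + cumsum(c(0, d[-n_events]))
    if (is.infinite(concentration)) {
      topics <- matrix(1 / n_topics, n_events, n_topics)
    } else {
      topics <- rdirichlet(n_events, rep(concentration, n_topics))
    }
    lmax <- round(max(d) * fs)
    basis <- smooth_basis(lmax, n_topics, fs)
    event_set(onset, d, topics = topics, phase = phase, basis = basis,
              fs = fs)
  })
}

# deterministic embedded event track: for event m at in-event sample tau,
# signal = basis[tau, ] %*% (w_m / ||w_m||); returns a length-n vector
embed_track <- function(event_set, n_samples, fs, weights = NULL) {
  ev <- event_set$events
  basis <- event_set$basis
  if (is.null(basis)) stop("event set carries no topic basis")
  w <- weights %||% event_set$topics
  track <- numeric(n_samples)
  for (m in seq_len(nrow(ev))) {
    len <- round(ev$duration_s[m] * fs)
    i0 <- round(ev$onset_s[m] * fs)
    idx <- i0 + seq_len(len)
    wm <- w[m, ] / sqrt(sum(w[m, ]^2))
    track[idx] <- basis[seq_len(len), , drop = FALSE] %*% wm
  }
  track
}

# offset- (or midpoint-) locked hemodynamic transients
boundary_track <- function(event_set, n_samples, fs, amp,
                           at = c("offset", "midpoint")) {
  at <- match.arg(at)
  track <- numeric(n_samples)
  if (amp == 0) return(track)
  kern <- boundary_kernel(fs) * amp
  anchors <- switch(at,
    offset = event_set$events$offset_s,
    midpoint = (event_set$events$onset_s + event_set$events$offset_s) / 2)
  for (a in anchors) {
    i0 <- round(a * fs)
    idx <- i0 + seq_along(kern)
    keep <- idx >= 1 & idx <= n_samples
    track[idx[keep]] <- track[idx[keep]] + kern[keep]
  }
  track
}

#' Simulate one participant's recording
#'
#' Builds a channel x time HbO-like matrix over the event set's session. The
#' embedded channel carries `sqrt(rho) * s_m(t) + sqrt(1 - rho) * noise`,
#' where `s_m` mixes the shared topic-basis waveforms with event `m`'s topic
#' weights, so the expected inter-subject correlation between events tracks
#' their topic cosine similarity. All channels carry AR(1) noise plus the
#' subject's global physiological component; hemodynamic transients of
#' amplitude `boundary_amp` are anchored at each event offset on the
#' embedded channel. For `role = "teacher"` the deterministic (embedded +
#' boundary) structure is advanced by `teacher_lead` seconds.
#'
#' @param event_set an [event_set()] from [make_event_set()].
#' @param config a [synth_config()].
#' @param role `"student"` or `"teacher"`.
#' @param seed integer seed for this recording's noise.
#' @param subject_id identifier stored in the recording.
#' @return a [recording()]; its `truth` element stores the injected global
#'   series, channel gains, the subject's embedding weights and an (empty)
#'   artifact mask.
#' @export
simulate_recording <- function(event_set, config, role = "student",
                               seed = NULL, subject_id = NULL) {
  validate_synth_config(config)
  fs <- config$fs
  if (abs(fs - event_set$fs) > 1e-9) {
    stop("config fs and event set fs disagree")
  }
  span_end <- max(event_set$events$offset_s)
  # at least 40 s of tail for boundary windows; padded to a 5-smooth sample
  # count so FFT-based surrogates stay O(n log n)
  n <- stats::nextn(round((span_end + 40) * fs), factors = c(2, 3, 5))
  if (round(config$teacher_lead * fs) >= n) {
    stop("invalid config: teacher_lead exceeds the recording length")
  }
  role <- match.arg(role, c("student", "teacher"))
  subject_id <- subject_id %||% if (role == "teacher") "T1" else "S1"
  with_seed(seed, {
    rho <- config$embed_strength
    w <- event_set$topics
    if (config$subject_distortion > 0) {
      w <- distort_topics(w, config$subject_distortion)
    }
    det <- sqrt(rho) * embed_track(event_set, n, fs, weights = w) +
      boundary_track(event_set, n, fs, config$boundary_amp,
                     config$boundary_at)
    if (role == "teacher" && config$teacher_lead > 0) {
      k <- round(config$teacher_lead * fs)
      det <- c(det[-seq_len(k)], numeric(k))   # advance in time
    }
    g <- ar1_series(n, 0.97)
    g <- g / sd(g)
    gains <- runif(config$n_channels, 0.5, 1.5)
    dat <- matrix(0, config$n_channels, n)
    for (c in seq_len(config$n_channels)) {
      eps <- ar1_series(n, config$noise_ar)
      mix <- eps + gains[c] * config$global_amp * g
      if (c == config$embed_channel) {
        dat[c, ] <- det + sqrt(1 - rho) * mix / sd(mix)
      } else {
        dat[c, ] <- mix
      }
    }
    rec <- recording(dat, fs, subject_id = subject_id, role = role)
    rec$truth <- list(global = g, gains = gains, weights = w,
                      artifact_mask = matrix(FALSE, config$n_channels, n))
    rec
  })
}

# Dirichlet resampling around a set of topic vectors; larger distortion =
# smaller concentration = noisier copies
distort_topics <- function(topics, distortion) {
  if (distortion == 0) return(topics)
  k <- ncol(topics)
  conc <- k / distortion
  out <- topics
  for (m in seq_len(nrow(topics))) {
    v <- topics[m, ] / sum(topics[m, ])
    out[m, ] <- rdirichlet(1, conc * v)
  }
  out
}

#' Inject square motion spikes into a recording
#'
#' Adds `n_spikes` square pulses of amplitude `spike_amp` (in units of the
#' channel's SD) at random positions on one channel and returns both the
#' corrupted recording and the ground-truth artifact mask, so that the QC
#' detection rule can be tested against known truth.
#'
#' @param rec a [recording()].
#' @param n_spikes number of spikes.
#' @param spike_amp spike amplitude as a multiple of the channel SD (should
#'   be much larger than 1 to count as an artifact).
#' @param channel channel index to corrupt.
#' @param width_s spike width in seconds. Spikes are brief relative to the
#'   10 s QC window by design; long dense excursions would inflate the
#'   window SD and mask themselves.
#' @param seed integer seed.
#' @return `list(recording, mask)` where `mask` is a channel x time logical
#'   matrix, `TRUE` inside injected spikes.
#' @export
inject_artifacts <- function(rec, n_spikes, spike_amp, channel = 1,
                             width_s = 0.2, seed = NULL) {
  n <- ncol(rec$data)
  w <- max(1, round(width_s * rec$fs))
  if (n_spikes * w > n) stop("requested spikes exceed the recording length")
  mask <- matrix(FALSE, nrow(rec$data), n)
  if (n_spikes == 0) return(list(recording = rec, mask = mask))
  with_seed(seed, {
    s <- sd(rec$data[channel, ])
    # one spike per equal segment of the recording (jittered), with
    # alternating sign, so spikes spread out like isolated motion events
    seg <- floor(n / n_spikes)
    starts <- (seq_len(n_spikes) - 1L) * seg +
      sample.int(max(seg - w, 1), n_spikes, replace = TRUE)
    sgn <- rep_len(c(1, -1), n_spikes)
    for (i in seq_along(starts)) {
      idx <- starts[i]:min(starts[i] + w - 1, n)
      rec$data[channel, idx] <- rec$data[channel, idx] +
        sgn[i] * spike_amp * s
      mask[channel, idx] <- TRUE
    }
    if (!is.null(rec$truth)) {
      rec$truth$artifact_mask <- rec$truth$artifact_mask | mask
    }
    list(recording = rec, mask = mask)
  })
}

#' Simulate per-student recall records
#'
#' Each student recalls each event independently with probability
#' `recall_probs` (scalar or per-event vector); correctly recalled events are
#' coded 1, all others 0. A per-student recalled-event similarity matrix is
#' built from the student's (optionally distorted) topic vectors over the
#' recalled events only, with an availability mask covering jointly recalled
#' pairs.
#'
#' @param event_set an [event_set()] with topic vectors.
#' @param recall_probs recall probability in `[0, 1]`, scalar or length-M.
#' @param distortion non-negative Dirichlet distortion of the recalled topic
#'   vectors (0 = faithful recall).
#' @param n_students number of students.
#' @param seed integer seed.
#' @return a list of `recall_record` objects with elements `recalled`
#'   (logical M-vector) and `matrix` (a [sim_matrix()] of kind `"recalled"`).
#' @export
simulate_recall <- function(event_set, recall_probs, distortion = 0,
                            n_students = 1, seed = NULL) {
  m <- n_events(event_set)
  p <- rep_len(recall_probs, m)
  if (any(p < 0 | p > 1)) stop("recall_probs must lie in [0, 1]")
  with_seed(seed, {
    lapply(seq_len(n_students), function(s) {
      recalled <- runif(m) < p
      w <- distort_topics(event_set$topics, distortion)
      vals <- cosine_matrix(w)
      mask <- outer(recalled, recalled, `&`)
      vals[!mask] <- NA_real_
      rec <- list(recalled = recalled,
                  matrix = sim_matrix(vals, mask, kind = "recalled"),
                  student = paste0("S", s))
      class(rec) <- "recall_record"
      rec
    })
  })
}

#' @export
print.recall_record <- function(x, ...) {
  cat(sprintf("<recall_record> %s: %d/%d events recalled\n",
              x$student, sum(x$recalled), length(x$recalled)))
  invisible(x)
}

#' Simulate a full classroom cohort
#'
#' Generates one event set, `n_students` student recordings, one teacher
#' recording and the ground truth needed for parameter-recovery tests.
#'
#' @param config a [synth_config()].
#' @param recall_probs optional recall probability (see [simulate_recall()]);
#'   `NULL` skips recall simulation.
#' @param recall_distortion distortion of recalled topic vectors.
#' @return a list with elements `event_set`, `students` (list of
#'   recordings), `teacher`, `knowledge` (a [sim_matrix()]), `recall`
#'   (list of recall records or `NULL`) and `config`.
#' @export
simulate_cohort <- function(config, recall_probs = NULL,
                            recall_distortion = 0) {
  validate_synth_config(config)
  seed <- config$seed
  es <- make_event_set(config$n_events, config$n_topics,
                       config$duration_range, config$concentration,
                       seed = child_seed(seed, 1), fs = config$fs,
                       mean_duration_s = config$mean_duration_s)
  students <- lapply(seq_len(config$n_students), function(i) {
    simulate_recording(es, config, role = "student",
                       seed = child_seed(seed, 100 + i),
                       subject_id = paste0("S", i))
  })
  teacher <- simulate_recording(es, config, role = "teacher",
                                seed = child_seed(seed, 99),
                                subject_id = "T1")
  recall <- if (!is.null(recall_probs)) {
    simulate_recall(es, recall_probs, recall_distortion,
                    n_students = config$n_students,
                    seed = child_seed(seed, 7))
  }
  list(event_set = es, students = students, teacher = teacher,
       knowledge = cosine_knowledge_matrix(es), recall = recall,
       config = config)
}
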