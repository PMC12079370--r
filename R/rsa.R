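## Inter-subject event-level RSA: brain matrices, Spearman statistics,
## permutation nulls and FDR.

# channel series over the (retained) phase window; event onsets are
# referenced to the start of this window
channel_series <- function(rec, channel, phase = 1) {
  rec$data[channel, phase_samples(rec, phase)]
}

#' Extract per-event signal segments
#'
#' Cuts the preprocessed signal of one channel into one series per knowledge
#' event (half-open `[onset, offset)` windows, so an event of `d` seconds at
#' `fs` Hz yields `round(d * fs)` samples).
#'
#' @param rec a [recording()].
#' @param event_set an [event_set()] referenced to the recording's phase.
#' @param channel channel index.
#' @param phase phase window name or index.
#' @return a list of numeric vectors, one per event.
#' @export
extract_event_series <- function(rec, event_set, channel, phase = 1) {
  xs <- channel_series(rec, channel, phase)
  ev <- event_set$events
  fs <- rec$fs
  lapply(seq_len(nrow(ev)), function(m) {
    i0 <- round(ev$onset_s[m] * fs)
    len <- round(ev$duration_s[m] * fs)
    if (i0 < 0 || i0 + len > length(xs)) {
      stop("event ", ev$event_id[m], " lies outside the recording span")
    }
    xs[i0 + seq_len(len)]
  })
}

# zero-padded Lmax x M event block from a phase-span series; lag_samples
# shifts the extraction window left (positive = read earlier samples, the
# teacher-precedes convention); out-of-span events are dropped (zeroed)
event_block <- function(xs, event_set, fs, lag_samples = 0) {
  ev <- event_set$events
  m <- nrow(ev)
  lens <- as.integer(round(ev$duration_s * fs))
  lmax <- max(lens)
  E <- matrix(0, lmax, m)
  dropped <- logical(m)
  for (i in seq_len(m)) {
    i0 <- round(ev$onset_s[i] * fs) - lag_samples
    if (i0 < 0 || i0 + lens[i] > length(xs)) {
      dropped[i] <- TRUE
      next
    }
    E[seq_len(lens[i]), i] <- xs[i0 + seq_len(lens[i])]
  }
  list(E = E, lens = lens, dropped = dropped)
}

# Lmax x M x N cube of one channel's event blocks across a cohort
cohort_cube <- function(xs_list, event_set, fs) {
  b1 <- event_block(xs_list[[1]], event_set, fs)
  cube <- array(0, dim = c(nrow(b1$E), length(b1$lens), length(xs_list)))
  cube[, , 1] <- b1$E
  if (length(xs_list) > 1) {
    for (s in 2:length(xs_list)) {
      cube[, , s] <- event_block(xs_list[[s]], event_set, fs)$E
    }
  }
  list(cube = cube, lens = b1$lens)
}

# precomputed extraction map: source sample indices and destination cells of
# the zero-padded block, shared by all subjects (used by the permutation
# engine, where the same extraction runs hundreds of times)
block_map <- function(event_set, fs, n_samples) {
  ev <- event_set$events
  m <- nrow(ev)
  lens <- as.integer(round(ev$duration_s * fs))
  lmax <- max(lens)
  src <- integer(0)
  dst <- integer(0)
  for (i in seq_len(m)) {
    i0 <- round(ev$onset_s[i] * fs)
    if (i0 < 0 || i0 + lens[i] > n_samples) {
      stop("event ", ev$event_id[i], " lies outside the recording span")
    }
    src <- c(src, i0 + seq_len(lens[i]))
    dst <- c(dst, (i - 1L) * lmax + seq_len(lens[i]))
  }
  list(src = src, dst = dst, lens = lens, lmax = lmax, m = m)
}

# fill an Lmax x M x N cube from an n x N series matrix via the map
cube_from_matrix <- function(X, map) {
  n_sub <- ncol(X)
  cube <- array(0, dim = c(map$lmax, map$m, n_sub))
  off <- rep((seq_len(n_sub) - 1L) * (map$lmax * map$m),
             each = length(map$dst))
  cube[rep(map$dst, n_sub) + off] <- X[map$src, ]
  cube
}

# columnwise surrogate of an n x N series matrix
surrogate_matrix <- function(X, method) {
  n <- nrow(X)
  if (method == "phase_randomize") {
    F <- stats::mvfft(X)
    half <- floor((n - 1) / 2)
    rot <- matrix(complex(modulus = 1,
                          argument = runif(half * ncol(X), 0, 2 * pi)),
                  half, ncol(X))
    pos <- 2:(half + 1)
    F[pos, ] <- F[pos, ] * rot
    F[n + 2 - pos, ] <- Conj(F[pos, ])
    Re(stats::mvfft(F, inverse = TRUE)) / n
  } else if (method == "time_shuffle") {
    for (j in seq_len(ncol(X))) X[, j] <- X[sample.int(n), j]
    X
  } else {
    for (j in seq_len(ncol(X))) {
      X[, j] <- circular_shift(X[, j])
    }
    X
  }
}

#' Inter-subject pair brain matrix
#'
#' For two participants, correlates event `m` of one with event `n` of the
#' other (Pearson) and averages the two directions, yielding a symmetric
#' event-by-event brain activity matrix. Inter-subject correlation is used
#' so that the autocorrelation of a single participant's hemoglobin signal
#' cannot alias into the event similarities. Series of unequal duration are
#' truncated to the shorter length, anchored at event onset. Cells with
#' fewer than 3 overlapping samples (or degenerate variance) are masked; the
#' diagonal is masked as ignored.
#'
#' @param rec_i,rec_j two [recording()]s covering the events.
#' @param event_set an [event_set()].
#' @param channel channel index (same in both recordings).
#' @param phase phase window.
#' @return a [sim_matrix()] of kind `"brain"`.
#' @export
pair_brain_matrix <- function(rec_i, rec_j, event_set, channel, phase = 1) {
  bi <- event_block(channel_series(rec_i, channel, phase), event_set,
                    rec_i$fs)
  bj <- event_block(channel_series(rec_j, channel, phase), event_set,
                    rec_j$fs)
  if (any(bi$dropped) || any(bj$dropped)) {
    stop("events outside the recording span")
  }
  C <- cpp_pair_corr(bi$E, bj$E, bi$lens)
  P <- (C + t(C)) / 2
  mask <- is.finite(P)
  diag(mask) <- FALSE
  P[!mask] <- NA_real_
  sim_matrix(P, mask, kind = "brain")
}

#' Per-subject brain matrices for a cohort
#'
#' Computes the symmetrized inter-subject pair matrix for every unordered
#' pair of participants, then averages, for each participant, the N - 1
#' matrices in which they take part, giving one brain matrix per subject.
#'
#' @param recs list of [recording()]s (N >= 2).
#' @param event_set an [event_set()].
#' @param channel channel index.
#' @param phase phase window.
#' @return list with `subject` (list of N [sim_matrix()]s), `pairs`
#'   (G x 2 index matrix) and `pair_mats` (list of G [sim_matrix()]s).
#' @export
subject_brain_matrices <- function(recs, event_set, channel, phase = 1) {
  n <- length(recs)
  if (n < 2) stop("need at least 2 participants")
  cc <- cohort_cube(lapply(recs, channel_series, channel, phase),
                    event_set, rec_fs(recs))
  pm <- cpp_all_pair_mats(cc$cube, cc$lens)
  pairs <- t(combn(n, 2))
  to_sim <- function(v) {
    mask <- is.finite(v)
    diag(mask) <- FALSE
    v[!mask] <- NA_real_
    sim_matrix(v, mask, kind = "brain")
  }
  pair_mats <- lapply(seq_len(dim(pm)[3]), function(g) to_sim(pm[, , g]))
  subject <- lapply(seq_len(n), function(i) {
    take <- which(pairs[, 1] == i | pairs[, 2] == i)
    acc <- Reduce(`+`, lapply(take, function(g) {
      v <- pm[, , g]
      v[!is.finite(v)] <- 0
      v
    }))
    cnt <- Reduce(`+`, lapply(take, function(g) is.finite(pm[, , g]) * 1))
    to_sim(ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_))
  })
  list(subject = subject, pairs = pairs, pair_mats = pair_mats)
}

#' Mean brain matrix of one subject against the rest of a cohort
#'
#' @param i subject index within `recs`.
#' @inheritParams subject_brain_matrices
#' @return a [sim_matrix()] of kind `"brain"`.
#' @export
subject_brain_matrix <- function(i, recs, event_set, channel, phase = 1) {
  subject_brain_matrices(recs, event_set, channel, phase)$subject[[i]]
}

rec_fs <- function(recs) {
  fs <- unique(vapply(recs, `[[`, numeric(1), "fs"))
  if (length(fs) != 1) stop("recordings disagree on sampling rate")
  fs
}

#' Representational similarity between brain and knowledge matrices
#'
#' Spearman correlation between the strictly-lower triangles of the two
#' matrices, restricted to the intersection of their availability masks
#' (ties receive average ranks). Requires at least 3 jointly available
#' cells; otherwise `NA` is returned with attribute `flagged = TRUE`.
#'
#' @param brain a [sim_matrix()] (or plain matrix) of brain similarities.
#' @param knowledge a [sim_matrix()] (or plain matrix) of knowledge
#'   similarities.
#' @return Spearman rho (scalar).
#' @export
rsa_correlation <- function(brain, knowledge) {
  jl <- joint_lower(as_sim(brain, "brain"), as_sim(knowledge, "knowledge"))
  if (jl$n < 3) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  cor(jl$a, jl$b, method = "spearman")
}

# mean cross-subject RSA r for one channel; fast compiled path when every
# cell is available, masked R path otherwise
cohort_mean_rsa <- function(xs_list, event_set, fs, knowledge) {
  cc <- cohort_cube(xs_list, event_set, fs)
  kl <- lower_vec(knowledge$values)
  full <- all(knowledge$mask[lower.tri(knowledge$mask)]) && all(cc$lens >= 3)
  if (full) {
    r <- cpp_cohort_rsa(cc$cube, cc$lens, rank(kl))
    return(mean(r[is.finite(r)]))
  }
  pm <- cpp_all_pair_mats(cc$cube, cc$lens)
  n <- length(xs_list)
  pairs <- t(combn(n, 2))
  r <- vapply(seq_len(n), function(i) {
    take <- which(pairs[, 1] == i | pairs[, 2] == i)
    acc <- apply(pm[, , take, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    mask <- is.finite(acc)
    diag(mask) <- FALSE
    rsa_correlation(sim_matrix(replace(acc, !mask, NA_real_), mask, "brain"),
                    knowledge)
  }, numeric(1))
  mean(r[is.finite(r)])
}

#' Permutation null for one channel's RSA statistic
#'
#' Builds the null distribution of the cross-subject mean RSA r by
#' surrogate-transforming every participant's channel series (phase
#' randomization by default, time shuffling and circular shifts
#' selectable), re-running the full inter-subject matrix pipeline on the
#' surrogates, and applying the one-tailed p-value formula
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param recs list of student [recording()]s.
#' @param event_set an [event_set()].
#' @param knowledge knowledge [sim_matrix()].
#' @param channel channel index.
#' @param n_perm number of surrogate iterations (>= 1).
#' @param method surrogate type (see [surrogate_series()]).
#' @param seed integer seed.
#' @param phase phase window.
#' @return list with `observed`, `null` and `p`.
#' @export
permutation_null <- function(recs, event_set, knowledge, channel,
                             n_perm = 1000,
                             method = c("phase_randomize", "time_shuffle",
                                        "circular_shift"),
                             seed = NULL, phase = 1) {
  method <- match.arg(method)
  if (n_perm < 1) stop("n_perm must be at least 1")
  knowledge <- as_sim(knowledge, "knowledge")
  fs <- rec_fs(recs)
  xs_list <- lapply(recs, channel_series, channel, phase)
  X <- do.call(cbind, xs_list)
  kl <- lower_vec(knowledge$values)
  map <- block_map(event_set, fs, nrow(X))
  fast <- all(knowledge$mask[lower.tri(knowledge$mask)]) &&
    all(map$lens >= 3)
  stat <- if (fast) {
    kr <- rank(kl)
    function(X) {
      r <- cpp_cohort_rsa(cube_from_matrix(X, map), map$lens, kr)
      mean(r[is.finite(r)])
    }
  } else {
    function(X) {
      cohort_mean_rsa(lapply(seq_len(ncol(X)), function(s) X[, s]),
                      event_set, fs, knowledge)
    }
  }
  observed <- stat(X)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat(surrogate_matrix(X, method)),
           numeric(1))
  })
  list(observed = observed, null = null,
       p = permutation_pvalue(observed, null))
}

#' Inter-subject representational similarity analysis
#'
#' The package's central fit: for each channel, per-subject brain matrices
#' are built by inter-subject event correlation, correlated (Spearman, lower
#' triangles) with the knowledge matrix, and averaged across subjects; the
#' cross-subject mean r is tested against a surrogate permutation null and
#' the per-channel p-values are corrected by Benjamini-Hochberg FDR.
#'
#' @param x a cohort list (as from [simulate_cohort()] /
#'   [preprocess_cohort()]) or a list of student [recording()]s.
#' @param event_set an [event_set()]; defaults to `x$event_set`.
#' @param knowledge knowledge [sim_matrix()]; defaults to `x$knowledge` or
#'   the cosine matrix of the event set's topic vectors.
#' @param channels channel indices to analyze (default: all).
#' @param n_perm permutation iterations per channel (0 skips inference).
#' @param method surrogate type (see [surrogate_series()]).
#' @param q FDR threshold.
#' @param seed integer seed (fans out per channel).
#' @param phase phase window.
#' @return an object of class `isrsa` with a per-channel results table
#'   (`channel`, `label`, `r`, `p`, `q_value`, `significant`), per-subject
#'   r values and the null distributions.
#' @export
isrsa <- function(x, event_set = NULL, knowledge = NULL, channels = NULL,
                  n_perm = 1000,
                  method = c("phase_randomize", "time_shuffle",
                             "circular_shift"),
                  q = 0.05, seed = NULL, phase = 1) {
  method <- match.arg(method)
  recs <- if (!is.null(x$students)) x$students else x
  event_set <- event_set %||% x$event_set
  knowledge <- as_sim(knowledge %||% x$knowledge %||%
                        cosine_knowledge_matrix(event_set), "knowledge")
  channels <- channels %||% seq_len(n_channels(recs[[1]]))
  labels <- recs[[1]]$channel_labels[channels]
  fs <- rec_fs(recs)
  per_subject <- matrix(NA_real_, length(recs), length(channels),
                        dimnames = list(NULL, labels))
  r_mean <- p <- rep(NA_real_, length(channels))
  nulls <- vector("list", length(channels))
  for (k in seq_along(channels)) {
    ch <- channels[k]
    sbm <- subject_brain_matrices(recs, event_set, ch, phase)
    per_subject[, k] <- vapply(sbm$subject, rsa_correlation,
                               numeric(1), knowledge)
    r_mean[k] <- mean(per_subject[, k][is.finite(per_subject[, k])])
    if (n_perm > 0) {
      pn <- permutation_null(recs, event_set, knowledge, ch,
                             n_perm = n_perm, method = method,
                             seed = child_seed(seed, ch), phase = phase)
      p[k] <- pn$p
      nulls[[k]] <- pn$null
    }
  }
  fdr <- if (n_perm > 0) fdr_correct(p, q) else
    list(q_values = rep(NA_real_, length(p)), significant = rep(NA, length(p)))
  structure(list(
    table = data.frame(channel = channels, label = labels, r = r_mean,
                       p = p, q_value = fdr$q_values,
                       significant = fdr$significant,
                       stringsAsFactors = FALSE),
    per_subject_r = per_subject, null = nulls,
    n_subjects = length(recs), n_events = n_events(event_set),
    n_perm = n_perm, method = method, q = q
  ), class = "isrsa")
}

#' @export
print.isrsa <- function(x, ...) {
  cat(sprintf("Inter-subject RSA: %d subjects, %d events, %d channel(s)\n",
              x$n_subjects, x$n_events, nrow(x$table)))
  if (x$n_perm > 0) {
    cat(sprintf("Permutation null: %s, %d iterations; BH-FDR at q < %.2f\n",
                x$method, x$n_perm, x$q))
  }
  best <- x$table[order(-x$table$r), , drop = FALSE]
  print(head(best, 5), row.names = FALSE, digits = 3)
  if (nrow(x$table) > 5) cat("... (", nrow(x$table), "channels )\n")
  invisible(x)
}

#' @export
summary.isrsa <- function(object, ...) {
  tab <- object$table
  cat(sprintf("Channels analyzed : %d\n", nrow(tab)))
  cat(sprintf("Mean RSA r        : %.4f (range %.4f to %.4f)\n",
              mean(tab$r), min(tab$r), max(tab$r)))
  if (object$n_perm > 0) {
    sig <- tab[which(tab$significant), , drop = FALSE]
    cat(sprintf("Significant (q < %.2f): %d channel(s)\n", object$q,
                nrow(sig)))
    if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
  }
  invisible(object$table)
}

#' @export
plot.isrsa <- function(x, ...) {
  tab <- x$table
  cols <- ifelse(tab$significant %in% TRUE, "firebrick", "grey60")
  graphics::barplot(tab$r, names.arg = tab$label, las = 2, col = cols,
                    ylab = "mean RSA r (Spearman)", border = NA, ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Write an RSA results table
#'
#' @param x an [isrsa()] fit.
#' @param path output TSV path (columns `channel`, `label`, `r`, `p`,
#'   `q_value`, `significant`).
#' @return `path`, invisibly.
#' @export
write_rsa_table <- function(x, path) {
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
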