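# small cohort fixtures used across the suite; all randomness is seeded

quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_students = 4, n_channels = 2, n_events = 8, n_topics = 6,
         duration_range = c(6, 20), embed_channel = 1,
         embed_strength = 0.5, boundary_amp = 0, global_amp = 0.5,
         noise_ar = 0.3, seed = 1L),
    list(...))
  do.call(synth_config, args)
}

quick_cohort <- function(...) simulate_cohort(quick_config(...))

# plain-R oracle for the inter-subject pair matrix: double loop over event
# pairs, truncation to the shorter series, two-direction average
oracle_pair_matrix <- function(rec_i, rec_j, event_set, channel) {
  si <- extract_event_series(rec_i, event_set, channel)
  sj <- extract_event_series(rec_j, event_set, channel)
  m <- length(si)
  out <- matrix(NA_real_, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      L <- min(length(si[[a]]), length(sj[[b]]))
      r1 <- cor(si[[a]][1:L], sj[[b]][1:L])
      L2 <- min(length(sj[[a]]), length(si[[b]]))
      r2 <- cor(sj[[a]][1:L2], si[[b]][1:L2])
      out[a, b] <- (r1 + r2) / 2
    }
  }
  out
}

# hand Benjamini-Hochberg step-up, independent of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}
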