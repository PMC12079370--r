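test_that("artifact detection flags planted spikes and spares clean data", {
  rec <- recording(matrix(0, 2, 1200), fs = 10)
  qc <- detect_artifacts(rec)
  expect_equal(sum(qc$mask), 0)
  expect_false(any(qc$bad))

  co <- quick_cohort(seed = 21)
  rec <- co$students[[1]]
  n <- ncol(rec$data)
  # spikes covering ~6% of channel 1
  n_spk <- ceiling(0.06 * n / 2)
  spk <- inject_artifacts(rec, n_spk, 10, channel = 1, width_s = 0.2,
                          seed = 3)
  qc <- detect_artifacts(spk$recording)
  expect_true(qc$bad[1])
  expect_false(qc$bad[2])
  # detection recovers most of the planted mask
  hit <- sum(qc$mask[1, ] & spk$mask[1, ]) / sum(spk$mask[1, ])
  expect_gt(hit, 0.5)

  expect_error(detect_artifacts(recording(matrix(0, 1, 50), fs = 10)),
               "window")
})

test_that("subject exclusion follows the bad-channel fraction rule", {
  mk_qc <- function(n_bad) {
    cfg <- quick_config(n_channels = 22, n_students = 1, seed = 22)
    co <- simulate_cohort(cfg)
    rec <- co$students[[1]]
    n <- ncol(rec$data)
    n_spk <- ceiling(0.06 * n / 2)
    for (ch in seq_len(n_bad)) {
      rec <- inject_artifacts(rec, n_spk, 10, channel = ch,
                              seed = 30 + ch)$recording
    }
    detect_artifacts(rec)
  }
  qc8 <- mk_qc(8)                      # 8/22 = 36% bad
  expect_equal(sum(qc8$bad), 8)
  expect_true(qc8$excluded)
  qc6 <- mk_qc(6)                      # 6/22 = 27% bad
  expect_equal(sum(qc6$bad), 6)
  expect_false(qc6$excluded)
})

test_that("steady-state trimming shortens phases and re-references onsets", {
  rec <- recording(matrix(rnorm(6000), 1), fs = 10)   # 600 s
  tr <- trim_steady_state(rec, 15)
  expect_equal(unname(diff(tr$phase_windows$main)), 570)

  es <- event_set(onset_s = c(20, 40), duration_s = c(10, 10))
  es2 <- trim_events(es, 15)
  expect_equal(es2$events$onset_s, c(5, 25))

  short <- recording(matrix(rnorm(250), 1), fs = 10)  # 25 s
  expect_error(trim_steady_state(short, 15), "too short")
})

test_that("spatial PCA removes shared structure and the injected global", {
  x <- rnorm(800)
  rec <- recording(rbind(x, 2 * x + 1, -x), fs = 10)
  cl <- remove_global_pca(rec)
  expect_lt(max(abs(cl$data)), 1e-8)

  cfg <- quick_config(n_students = 1, n_channels = 22, global_amp = 2,
                      seed = 23)
  co <- simulate_cohort(cfg)
  rec <- co$students[[1]]
  cl <- remove_global_pca(rec)
  rs <- vapply(seq_len(22), function(c) {
    cor(cl$data[c, ], rec$truth$global)
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.1)
})

test_that("global removal leaves the embedded event signal recoverable", {
  for (s in 1:2) {
    cfg <- quick_config(n_students = 8, n_channels = 22, embed_channel = 3,
                        global_amp = 1, seed = 330 + s)
    co <- simulate_cohort(cfg)
    raw <- isrsa(co, channels = 3, n_perm = 0)$table$r
    co$students <- lapply(co$students, remove_global_pca)
    post <- isrsa(co, channels = 3, n_perm = 0)$table$r
    expect_gt(post, 0.6 * raw)
  }
})

test_that("band-pass attenuates out-of-band tones and passes in-band ones", {
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  mk <- function(f) recording(matrix(sin(2 * pi * f * t), 1), fs = fs)
  rms <- function(r) sqrt(mean(r$data[1, 1001:5000]^2))

  hi <- bandpass(mk(1))
  expect_lt(20 * log10(rms(hi) / sqrt(0.5)), -20)   # >= 20 dB down

  mid <- bandpass(mk(0.1))
  expect_lt(abs(rms(mid) / sqrt(0.5) - 1), 0.1)     # within 10%

  const <- bandpass(recording(matrix(5, 1, 3000), fs = fs))
  expect_lt(max(abs(const$data)), 1e-6)

  expect_error(bandpass(mk(1), lo = 0.1, hi = 6), "invalid band")
})

test_that("z-scoring standardizes, ignores affine shifts and is idempotent", {
  co <- quick_cohort(seed = 24)
  rec <- co$students[[1]]
  z1 <- zscore_recording(rec)
  idx <- seq_len(ncol(rec$data))
  for (c in 1:2) {
    expect_lt(abs(mean(z1$data[c, idx])), 1e-10)
    expect_lt(abs(sd(z1$data[c, idx]) - 1), 1e-10)
  }
  # affine transforms of a channel give identical z-scores
  aff <- rec
  aff$data[1, ] <- 3 * rec$data[1, ] - 7
  z2 <- zscore_recording(aff)
  expect_equal(z2$data[1, ], z1$data[1, ], tolerance = 1e-10)
  # idempotence
  z3 <- zscore_recording(z1)
  expect_lt(max(abs(z3$data[, idx] - z1$data[, idx])), 1e-12)
  # constant channel flagged and zeroed
  k <- rec
  k$data[2, ] <- 4
  zk <- zscore_recording(k)
  expect_true(all(zk$data[2, idx] == 0))
  expect_true(2 %in% attr(zk, "zero_channels"))
})

test_that("the composed pipeline keeps events aligned and output standardized", {
  cfg <- quick_config(n_students = 4, n_channels = 4, embed_channel = 2,
                      global_amp = 1, seed = 25)
  co <- simulate_cohort(cfg)
  pp <- preprocess_cohort(co)
  expect_length(pp$students, 4)
  expect_equal(nrow(pp$event_set$events), nrow(co$event_set$events))
  expect_identical(pp$event_set$events$event_id, co$event_set$events$event_id)
  expect_equal(pp$event_set$events$onset_s, co$event_set$events$onset_s - 15)
  rec <- pp$students[[1]]
  expect_true(all(is.finite(rec$data)))
  idx <- phase_window_idx <- seq(floor(rec$phase_windows$main[1] * rec$fs) + 1,
                                 floor(rec$phase_windows$main[2] * rec$fs))
  expect_lt(abs(sd(rec$data[1, idx]) - 1), 1e-8)
  # events remain inside the trimmed phase
  expect_true(all(pp$event_set$events$onset_s >= 0))
  ser <- extract_event_series(rec, pp$event_set, 1)
  expect_length(ser, nrow(pp$event_set$events))
})

test_that("QC decisions are taken on the raw pre-trim data", {
  co <- quick_cohort(seed = 26)
  rec <- co$students[[1]]
  n <- ncol(rec$data)
  # corrupt only the first 10 s, inside the span later trimmed away
  rec$data[1, 1:100] <- rec$data[1, 1:100] + 50
  qc_raw <- detect_artifacts(rec)
  expect_gt(sum(qc_raw$mask[1, 1:150]), 0)
  out <- preprocess(rec)
  expect_equal(out$qc$artifact_frac, qc_raw$artifact_frac)
})
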