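test_that("event sets respect duration bounds, ordering and determinism", {
  es <- make_event_set(26, 8, duration_range = c(6, 200), seed = 11)
  ev <- es$events
  expect_equal(nrow(ev), 26)
  expect_true(all(ev$duration_s >= 6 & ev$duration_s <= 200))
  expect_true(all(diff(ev$onset_s) > 0))
  # contiguous tiling: each event starts where the previous one ends
  expect_equal(ev$onset_s[-1], ev$offset_s[-26])
  es2 <- make_event_set(26, 8, duration_range = c(6, 200), seed = 11)
  expect_identical(es$events, es2$events)
  expect_identical(es$topics, es2$topics)

  expect_error(make_event_set(2, 8, seed = 1), "at least 3")
  expect_error(make_event_set(5, 8, duration_range = c(3, 20), seed = 1),
               "duration")
})

test_that("infinite topic concentration yields an all-ones knowledge matrix", {
  es <- make_event_set(6, 5, duration_range = c(6, 20),
                       concentration = Inf, seed = 2)
  km <- cosine_knowledge_matrix(es)
  expect_equal(unname(km$values), matrix(1, 6, 6))
})

test_that("noiseless rho = 1 pair matrix matches the analytic basis overlap", {
  cfg <- quick_config(n_students = 2, embed_strength = 1, global_amp = 0,
                      seed = 3)
  co <- simulate_cohort(cfg)
  pm <- pair_brain_matrix(co$students[[1]], co$students[[2]],
                          co$event_set, 1)
  es <- co$event_set
  fs <- cfg$fs
  lens <- round(es$events$duration_s * fs)
  m <- length(lens)
  analytic <- matrix(NA_real_, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      L <- min(lens[a], lens[b])
      wa <- es$topics[a, ] / sqrt(sum(es$topics[a, ]^2))
      wb <- es$topics[b, ] / sqrt(sum(es$topics[b, ]^2))
      analytic[a, b] <- cor(es$basis[1:L, ] %*% wa, es$basis[1:L, ] %*% wb)
    }
  }
  analytic <- (analytic + t(analytic)) / 2
  expect_lt(max(abs(pm$values[pm$mask] - analytic[pm$mask])), 1e-6)
})

test_that("rho = 0 recordings carry no inter-subject event correlation", {
  cfg <- quick_config(n_students = 6, embed_strength = 0, seed = 4)
  co <- simulate_cohort(cfg)
  pm <- pair_brain_matrix(co$students[[1]], co$students[[2]],
                          co$event_set, 1)
  vals <- pm$values[pm$mask]
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.05)
})

test_that("identical seeds reproduce identical cohorts", {
  co1 <- quick_cohort(seed = 9)
  co2 <- quick_cohort(seed = 9)
  expect_identical(co1$students[[2]]$data, co2$students[[2]]$data)
  expect_identical(co1$teacher$data, co2$teacher$data)
  expect_identical(co1$event_set$events, co2$event_set$events)
})

test_that("teacher lead shifts the deterministic structure earlier", {
  cfg <- quick_config(n_students = 1, embed_strength = 1, global_amp = 0,
                      teacher_lead = 5, seed = 6)
  co <- simulate_cohort(cfg)
  k <- round(5 * cfg$fs)
  stud <- co$students[[1]]$data[1, ]
  teach <- co$teacher$data[1, ]
  n <- length(stud)
  expect_equal(teach[1:(n - k)], stud[(k + 1):n], tolerance = 1e-12)
  bad <- quick_config(teacher_lead = 1e7)
  expect_error(simulate_recording(co$event_set, bad, role = "teacher"),
               "teacher_lead")
})

test_that("offset-locked transients raise post-offset over mid-event activity", {
  cfg <- quick_config(n_students = 8, embed_strength = 0, boundary_amp = 2,
                      duration_range = c(6, 60), seed = 7)
  co <- simulate_cohort(cfg)
  diffs <- vapply(co$students, function(r) {
    boundary_effect(r, co$event_set, 1, window_s = 6)$difference
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("artifact injection returns an exact truth mask", {
  co <- quick_cohort(seed = 8)
  rec <- co$students[[1]]

  clean <- inject_artifacts(rec, 0, 10, seed = 1)
  expect_identical(clean$recording$data, rec$data)
  expect_false(any(clean$mask))

  one <- inject_artifacts(rec, 1, 10, channel = 2, width_s = 0.5, seed = 2)
  expect_equal(sum(one$mask), 5)
  expect_true(all(one$mask[2, ][one$mask[2, ]]))
  changed <- one$recording$data != rec$data
  expect_identical(unname(which(changed)), unname(which(one$mask)))

  expect_error(inject_artifacts(rec, 1e6, 10, seed = 3), "exceed")
})

test_that("recall simulation reproduces the knowledge matrix when faithful", {
  es <- make_event_set(8, 6, duration_range = c(6, 20), seed = 10)
  km <- cosine_knowledge_matrix(es)
  rr <- simulate_recall(es, recall_probs = 1, distortion = 0,
                        n_students = 2, seed = 1)
  expect_true(all(rr[[1]]$recalled))
  expect_equal(unname(rr[[1]]$matrix$values), unname(km$values), tolerance = 1e-12)
  expect_true(all(rr[[1]]$matrix$mask))

  none <- simulate_recall(es, recall_probs = 0, n_students = 1, seed = 1)
  expect_false(any(none[[1]]$recalled))
  expect_false(any(none[[1]]$matrix$mask))
  # a student with no recalled events cannot be scored downstream
  expect_true(is.na(decode_similarity(none[[1]]$matrix, km)))
})

test_that("recovered RSA strength increases with the embedding strength", {
  rhos <- c(0, 0.5, 1)
  seeds <- 1:4
  mean_r <- vapply(rhos, function(rho) {
    mean(vapply(seeds, function(s) {
      cfg <- quick_config(n_students = 8, n_channels = 1,
                          embed_strength = rho, seed = 100 + s)
      co <- simulate_cohort(cfg)
      isrsa(co, channels = 1, n_perm = 0)$table$r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("channels without an embedded signal show no systematic RSA", {
  r <- vapply(1:20, function(s) {
    cfg <- quick_config(n_students = 8, n_channels = 2, embed_channel = 1,
                        embed_strength = 0.5, seed = 200 + s)
    co <- simulate_cohort(cfg)
    isrsa(co, channels = 2, n_perm = 0)$table$r
  }, numeric(1))
  expect_lt(abs(mean(r)), 2 * sd(r) / sqrt(length(r)))
})
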