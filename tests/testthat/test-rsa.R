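test_that("event extraction returns one window per event at the right length", {
  rec <- recording(matrix(seq_len(1000), 1), fs = 10)
  es <- event_set(c(10, 30, 50), c(20, 20, 20))
  ser <- extract_event_series(rec, es, 1)
  expect_length(ser, 3)
  expect_length(ser[[1]], 200)
  expect_equal(ser[[1]][1], 101)       # sample at t = 10 s (0-based time)

  tiling <- event_set(c(0, 20, 50), c(20, 30, 50))
  ser2 <- extract_event_series(rec, tiling, 1)
  expect_equal(unlist(ser2), seq_len(1000))

  beyond <- event_set(c(90, 95), c(4, 10))
  expect_error(extract_event_series(rec, beyond, 1), "outside")
})

test_that("pair brain matrices agree with the plain-R truncation oracle", {
  co <- quick_cohort(seed = 31)
  pm <- pair_brain_matrix(co$students[[1]], co$students[[2]],
                          co$event_set, 1)
  oracle <- oracle_pair_matrix(co$students[[1]], co$students[[2]],
                               co$event_set, 1)
  off <- lower.tri(oracle) | upper.tri(oracle)
  expect_equal(pm$values[off], oracle[off], tolerance = 1e-12)
  # exact symmetry by construction, diagonal masked as ignored
  expect_identical(pm$values[pm$mask], t(pm$values)[t(pm$mask)])
  expect_false(any(diag(pm$mask)))

  # self-pairing puts each event's perfect self-correlation on the diagonal
  self <- oracle_pair_matrix(co$students[[1]], co$students[[1]],
                             co$event_set, 1)
  expect_equal(unname(diag(self)), rep(1, nrow(self)), tolerance = 1e-12)
})

test_that("subject matrices average the pairwise matrices", {
  co <- quick_cohort(n_students = 3, seed = 32)
  sbm <- subject_brain_matrices(co$students, co$event_set, 1)
  o12 <- oracle_pair_matrix(co$students[[1]], co$students[[2]],
                            co$event_set, 1)
  o13 <- oracle_pair_matrix(co$students[[1]], co$students[[3]],
                            co$event_set, 1)
  expect_equal(sbm$subject[[1]]$values[sbm$subject[[1]]$mask],
               ((o12 + o13) / 2)[sbm$subject[[1]]$mask], tolerance = 1e-12)

  # N = 2: the subject matrix is the single pair matrix
  two <- subject_brain_matrices(co$students[1:2], co$event_set, 1)
  expect_equal(two$subject[[1]]$values, two$pair_mats[[1]]$values)

  # permuting the cohort leaves each subject's matrix unchanged
  perm <- subject_brain_matrices(co$students[c(3, 1, 2)], co$event_set, 1)
  expect_equal(perm$subject[[2]]$values, sbm$subject[[1]]$values,
               tolerance = 1e-12)

  expect_error(subject_brain_matrices(co$students[1], co$event_set, 1),
               "at least 2")
})

test_that("rsa_correlation is a masked lower-triangle Spearman", {
  co <- quick_cohort(seed = 33)
  km <- co$knowledge
  expect_equal(rsa_correlation(km, km), 1)
  rev <- sim_matrix(-km$values, kind = "brain")
  expect_equal(rsa_correlation(rev, km), -1)

  # 4x4 hand case vs explicit rank computation
  b <- matrix(0, 4, 4)
  b[lower.tri(b)] <- c(0.3, -0.1, 0.7, 0.2, 0.5, 0.05)
  b <- b + t(b)
  k <- matrix(0, 4, 4)
  k[lower.tri(k)] <- c(0.9, 0.1, 0.6, 0.3, 0.2, 0.8)
  k <- k + t(k); diag(k) <- 1
  expected <- cor(rank(b[lower.tri(b)]), rank(k[lower.tri(k)]))
  expect_equal(rsa_correlation(sim_matrix(b, kind = "brain"),
                               sim_matrix(k, kind = "knowledge")),
               expected)

  # invariance under monotone transforms of either side
  expect_equal(rsa_correlation(sim_matrix(tanh(b), kind = "brain"),
                               sim_matrix(k, kind = "knowledge")),
               expected)

  # masking: fewer than 3 joint cells is flagged undefined
  mask <- matrix(TRUE, 4, 4)
  mask[lower.tri(mask)][c(1, 2, 3, 4)] <- FALSE
  mask <- mask & t(mask)
  masked <- sim_matrix(replace(b, !mask, NA), mask, kind = "brain")
  out <- rsa_correlation(masked, sim_matrix(k, kind = "knowledge"))
  expect_true(is.na(out))
  expect_true(attr(out, "flagged"))
})

test_that("the permutation p-value follows the add-one formula", {
  expect_equal(permutation_pvalue(0.9, seq(0, 0.49, length.out = 99)),
               1 / 100)
  expect_equal(permutation_pvalue(-1, seq(0, 0.49, length.out = 99)), 1)
  # hand count: 3 of 7 nulls at or above the empirical value
  expect_equal(permutation_pvalue(0.5, c(0.5, 0.6, 0.7, 0.1, 0.2, 0.3, 0)),
               (1 + 3) / (1 + 7))
})

test_that("circular-shift nulls enumerate exactly when exhaustive", {
  x <- c(0.3, -1.2, 0.5, 2.1, -0.4, 0.9)
  y <- c(1.0, 0.2, -0.3, 0.8, -1.1, 0.4)
  stat <- function(s) cor(s, y)
  exhaustive <- vapply(1:5, function(k) {
    cor(c(x[(k + 1):6], x[1:k]), y)
  }, numeric(1))
  mc <- perm_null_series(x, stat, n_perm = 5, method = "circular_shift",
                         seed = 5)
  expect_equal(sort(mc$null), sort(exhaustive))
  expect_equal(mc$p, permutation_pvalue(cor(x, y), exhaustive))
  ex <- perm_null_series(x, stat, method = "circular_shift",
                         exhaustive = TRUE)
  expect_equal(sort(ex$null), sort(exhaustive))
})

test_that("surrogates preserve spectrum or sample multiset as appropriate", {
  x <- rnorm(240)
  set.seed(1)
  pr <- phase_randomize(x)
  expect_false(isTRUE(all.equal(pr, x)))
  expect_equal(Mod(fft(pr)), Mod(fft(x)), tolerance = 1e-8)
  set.seed(2)
  expect_equal(sort(time_shuffle(x)), sort(x))
  set.seed(3)
  expect_equal(sort(circular_shift(x)), sort(x))
})

test_that("BH correction matches the hand step-up and keeps ordering", {
  single <- fdr_correct(0.01)
  expect_equal(single$q_values, 0.01)
  p22 <- seq(0.01, 0.22, by = 0.01)
  out <- fdr_correct(p22)
  expect_equal(out$q_values, oracle_bh(p22))
  expect_true(all(diff(out$q_values[order(p22)]) >= -1e-12))
  ones <- fdr_correct(rep(1, 5))
  expect_false(any(ones$significant))
  empty <- fdr_correct(numeric(0))
  expect_length(empty$q_values, 0)
})

test_that("permutation nulls give small p for embedded and large for flat", {
  cfg <- quick_config(n_students = 8, n_channels = 2, embed_channel = 1,
                      embed_strength = 0.8, seed = 34)
  co <- simulate_cohort(cfg)
  pn <- permutation_null(co$students, co$event_set, co$knowledge, 1,
                         n_perm = 49, seed = 1)
  expect_equal(pn$p, 1 / 50)          # observed beats every null
  pn2 <- permutation_null(co$students, co$event_set, co$knowledge, 2,
                          n_perm = 49, seed = 2)
  expect_gt(pn2$p, 0.05)
  expect_error(permutation_null(co$students, co$event_set, co$knowledge, 1,
                                n_perm = 0), "n_perm")
})

test_that("isrsa assembles the per-channel table with FDR flags", {
  cfg <- quick_config(n_students = 6, n_channels = 3, embed_channel = 2,
                      embed_strength = 0.8, seed = 35)
  co <- simulate_cohort(cfg)
  fit <- isrsa(co, n_perm = 39, seed = 4)
  expect_s3_class(fit, "isrsa")
  expect_equal(nrow(fit$table), 3)
  expect_equal(which.max(fit$table$r), 2)
  expect_true(all(fit$table$p > 0 & fit$table$p <= 1))
  expect_equal(fit$table$q_value, oracle_bh(fit$table$p))
  # determinism under the same seed
  fit2 <- isrsa(co, n_perm = 39, seed = 4)
  expect_identical(fit$table, fit2$table)
  expect_output(print(fit), "Inter-subject RSA")
})

test_that("masked knowledge matrices (recall-phase RSA) use the joint cells", {
  co <- quick_cohort(n_students = 5, seed = 36)
  km <- co$knowledge
  # group-averaged recalled matrix with partial coverage
  rr <- simulate_recall(co$event_set, recall_probs = 0.4, distortion = 0.3,
                        n_students = 3, seed = 2)
  gm <- group_average_recall_matrix(rr)
  expect_false(all(gm$mask))
  pn <- permutation_null(co$students, co$event_set, gm, channel = 1,
                         n_perm = 5, seed = 3)
  manual <- vapply(
    subject_brain_matrices(co$students, co$event_set, 1)$subject,
    rsa_correlation, numeric(1), gm)
  expect_equal(pn$observed, mean(manual), tolerance = 1e-12)
  # and the fast full-mask path agrees with the manual route too
  pn_full <- permutation_null(co$students, co$event_set, km, channel = 1,
                              n_perm = 5, seed = 3)
  manual_full <- vapply(
    subject_brain_matrices(co$students, co$event_set, 1)$subject,
    rsa_correlation, numeric(1), km)
  expect_equal(pn_full$observed, mean(manual_full), tolerance = 1e-12)
})

test_that("boundary contrast is zero for constant signals and handles hands", {
  rec <- recording(matrix(1, 1, 2000), fs = 10)
  es <- event_set(c(20, 60, 100), c(40, 40, 40))
  be <- boundary_effect(rec, es, 1, window_s = 15)
  expect_equal(be$difference, 0)

  # textbook paired t on a hand list of differences
  d <- c(0.2, -0.1, 0.4, 0.3)
  g <- group_boundary_test(d)
  tt <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(g$t, tt, tolerance = 1e-12)
  expect_equal(g$p, 2 * pt(abs(tt), 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(g$d, mean(d) / sd(d))

  z <- group_boundary_test(c(0, 0, 0))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  const <- group_boundary_test(c(1, 1, 1))
  expect_true(const$degenerate)
  expect_true(is.na(const$t))
  expect_error(group_boundary_test(c(1, 2)), "at least 3")
})

test_that("events shorter than the window drop from the non-boundary set only", {
  rec <- recording(matrix(rnorm(3000), 1), fs = 10)
  es <- event_set(c(20, 30, 80), c(10, 50, 60))   # first is < 15 s
  be <- boundary_effect(rec, es, 1, window_s = 15)
  expect_equal(be$n_nonboundary_events, 2)
  expect_equal(be$n_boundary_events, 3)
})
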