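make_pairs <- function(n) t(combn(n, 2))

test_that("decoding recovers the knowledge matrix from faithful brain data", {
  co <- quick_cohort(seed = 41)
  km <- co$knowledge
  pairs <- make_pairs(4)
  exact <- lapply(seq_len(nrow(pairs)), function(g) {
    sim_matrix(km$values, kind = "brain")
  })
  dec <- loo_dyad_decode(exact, km, pairs)
  expect_length(dec$skipped, 0)
  expect_equal(unname(dec$coef[, "slope"]), rep(1, 6), tolerance = 1e-10)
  expect_equal(unname(dec$coef[, "intercept"]), rep(0, 6), tolerance = 1e-10)
  lt <- lower.tri(km$values)
  for (p in dec$per_student) {
    expect_equal(p$values[lt], km$values[lt], tolerance = 1e-10)
  }
})

test_that("decoding is invariant to affine rescaling of the brain values", {
  co <- quick_cohort(seed = 42)
  km <- co$knowledge
  pairs <- make_pairs(4)
  scaled <- lapply(seq_len(nrow(pairs)), function(g) {
    sim_matrix(pmin(0.9 * km$values - 0.05, 1), kind = "brain")
  })
  dec <- loo_dyad_decode(scaled, km, pairs)
  for (p in dec$per_student) {
    expect_equal(rsa_correlation(p, km), 1)
  }
})

test_that("held-out pairs never influence their own training fit", {
  cfg <- quick_config(n_students = 5, n_channels = 1, seed = 43)
  co <- simulate_cohort(cfg)
  sbm <- subject_brain_matrices(co$students, co$event_set, 1)
  dec <- loo_dyad_decode(sbm$pair_mats, co$knowledge, sbm$pairs)
  # perturb held-out pair 3's matrix: its own fold's coefficients must not
  # move, every other fold's must
  pert <- sbm$pair_mats
  v <- pert[[3]]$values
  v[pert[[3]]$mask] <- -v[pert[[3]]$mask]
  pert[[3]] <- sim_matrix(v, pert[[3]]$mask, kind = "brain")
  dec2 <- loo_dyad_decode(pert, co$knowledge, sbm$pairs)
  expect_equal(dec2$coef[3, ], dec$coef[3, ], tolerance = 1e-12)
  expect_false(any(abs(dec2$coef[-3, "slope"] - dec$coef[-3, "slope"]) < 1e-15))
})

test_that("zero-variance training predictors are flagged and skipped", {
  km <- quick_cohort(seed = 44)$knowledge
  flat <- lapply(1:6, function(g) {
    v <- matrix(0.5, nrow(km$values), ncol(km$values))
    diag(v) <- 1
    sim_matrix(v, kind = "brain")
  })
  dec <- loo_dyad_decode(flat, km, make_pairs(4))
  expect_equal(dec$skipped, 1:6)
  expect_true(all(vapply(dec$per_student, is.null, logical(1))))
})

test_that("decode similarity applies clipped Fisher z on joint cells", {
  km <- quick_cohort(seed = 45)$knowledge
  pred <- sim_matrix(km$values, kind = "predicted")
  expect_equal(decode_similarity(pred, km), atanh(1 - 1e-7))
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)

  # fewer than 3 jointly available cells -> flagged NA (as for students who
  # recalled fewer than 3 events)
  m <- nrow(km$values)
  mask <- matrix(FALSE, m, m)
  mask[1:2, 1:2] <- TRUE
  few <- sim_matrix(replace(km$values, !mask, NA), mask, kind = "predicted")
  out <- decode_similarity(few, km)
  expect_true(is.na(out))
  expect_true(attr(out, "flagged"))
})

test_that("group one-sample test matches the textbook formula", {
  z <- c(0.1, 0.2, 0.3)
  g <- group_one_sample_test(z)
  tt <- mean(z) / (sd(z) / sqrt(3))
  expect_equal(g$t, tt, tolerance = 1e-12)
  expect_equal(g$p, 2 * pt(abs(tt), 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(g$d, mean(z) / sd(z))
  zero <- group_one_sample_test(rep(0, 4))
  expect_equal(zero$t, 0)
  expect_error(group_one_sample_test(c(0.1, 0.2)), "at least 3")
})

test_that("neural pISC is maximal for identical and near zero for random", {
  km <- quick_cohort(seed = 46)$knowledge
  same <- lapply(1:4, function(i) sim_matrix(km$values, kind = "predicted"))
  z <- neural_pisc(same)
  expect_equal(z, rep(atanh(1 - 1e-7), 4))

  set.seed(7)
  indep <- replicate(500, {
    mean(neural_pisc(lapply(1:3, function(i) {
      u <- matrix(0, 6, 6)
      u[lower.tri(u)] <- rnorm(15)
      sim_matrix(u + t(u), kind = "predicted")
    })))
  })
  expect_lt(abs(mean(indep)), 2 * sd(indep) / sqrt(length(indep)))
})

test_that("behavioral pISC implements mean pairwise Jaccard", {
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 0)
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "length")

  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  b <- behavioral_pisc(m)
  expect_equal(as.numeric(b), rep(1 / 3, 3))
  # invariant to student ordering
  expect_equal(sort(behavioral_pisc(m[c(3, 1, 2), ])), sort(b))
  # empty pair contributes 0 and is flagged
  e <- behavioral_pisc(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)))
  expect_equal(e[1], 0)
  expect_gte(attr(e, "empty_pairs"), 1L)
})

test_that("partial correlation equals the two-stage residual oracle", {
  x <- c(2.1, 3.3, 1.2, 4.8, 3.9, 2.5)
  y <- c(1.0, 2.2, 0.8, 3.9, 3.1, 1.7)
  cv <- data.frame(age = c(23, 25, 22, 28, 27, 24),
                   ses = c(1.2, 0.8, 1.5, 0.3, 0.9, 1.1))
  pc <- partial_correlation(x, y, cv)
  rx <- residuals(lm(x ~ age + ses, data = cv))
  ry <- residuals(lm(y ~ age + ses, data = cv))
  r_oracle <- cor(rx, ry)
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  df <- 6 - 2 - 2
  t_oracle <- r_oracle * sqrt(df / (1 - r_oracle^2))
  expect_equal(pc$p, pt(t_oracle, df, lower.tail = FALSE), tolerance = 1e-12)

  # no covariates reduces to plain Pearson
  expect_equal(partial_correlation(x, y)$r, cor(x, y))
  # a correlation carried entirely by the covariate vanishes when the
  # covariate is controlled
  set.seed(1)
  age <- rnorm(40)
  x2 <- age + rnorm(40, sd = 0.3)
  y2 <- age + rnorm(40, sd = 0.3)
  expect_gt(cor(x2, y2), 0.7)
  pc0 <- partial_correlation(x2, y2, data.frame(age = age))
  expect_lt(abs(pc0$r), 0.35)
  expect_error(partial_correlation(x, y, cbind(cv$age, cv$age * 2)),
               "collinear")
})

test_that("end-to-end decoding recovers structure from an embedded cohort", {
  cfg <- quick_config(n_students = 8, n_channels = 1, n_events = 12,
                      embed_strength = 0.8, seed = 47)
  co <- simulate_cohort(cfg)
  dec <- decode_knowledge(co, channel = 1)
  expect_gt(mean(dec$table$spearman), 0.2)
  expect_lt(dec$group$p, 0.05)
  expect_length(predict(dec), 8)
  expect_output(print(dec), "Leave-one-dyad-out")
})
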