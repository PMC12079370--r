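## Leave-one-dyad-out decoding of knowledge structure, pISC and
## behavior-brain coupling.

#' Leave-one-dyad-out regression decoding
#'
#' Treats the G pair brain matrices as a population: each pair is held out
#' in turn, the remaining training pairs' matrices are averaged, and a
#' univariate least-squares regression (intercept + slope) of the knowledge
#' lower-triangle values on the averaged brain lower-triangle values is
#' fitted; applying the fit to the held-out pair's brain values yields that
#' pair's predicted knowledge matrix. Each student's N - 1 predictions are
#' then averaged into one predicted matrix per student. Pairs whose
#' training predictor has zero variance are flagged and skipped.
#'
#' @param pair_mats list of G pair [sim_matrix()]s (order matching `pairs`).
#' @param knowledge knowledge [sim_matrix()].
#' @param pairs G x 2 matrix of the student indices forming each pair.
#' @param n_students number of students N (default `max(pairs)`).
#' @return list with `per_student` (list of predicted [sim_matrix()]s),
#'   `per_pair` (list of predicted matrices per held-out pair), `coef`
#'   (per-pair intercept/slope) and `skipped` (flagged pair indices).
#' @export
loo_dyad_decode <- function(pair_mats, knowledge, pairs,
                            n_students = max(pairs)) {
  g <- length(pair_mats)
  if (g < 3) stop("need at least 3 pairs for leave-one-dyad-out decoding")
  stopifnot(nrow(pairs) == g)
  knowledge <- as_sim(knowledge, "knowledge")
  m <- nrow(knowledge$values)
  lt <- lower.tri(knowledge$values)
  pm <- lapply(pair_mats, function(x) as_sim(x, "brain"))
  # joint availability across all pairs and the knowledge matrix
  keep <- knowledge$mask & lt
  for (x in pm) keep <- keep & x$mask
  if (sum(keep) < 3) stop("fewer than 3 jointly available cells")
  kv <- knowledge$values[keep]
  bv <- vapply(pm, function(x) x$values[keep], numeric(sum(keep)))
  coefs <- matrix(NA_real_, g, 2, dimnames = list(NULL, c("intercept", "slope")))
  per_pair <- vector("list", g)
  skipped <- integer(0)
  for (h in seq_len(g)) {
    xbar <- rowMeans(bv[, -h, drop = FALSE])
    vx <- var(xbar)
    if (!is.finite(vx) || vx < 1e-14) {
      skipped <- c(skipped, h)
      next
    }
    slope <- cov(xbar, kv) / vx
    intercept <- mean(kv) - slope * mean(xbar)
    coefs[h, ] <- c(intercept, slope)
    pred_vec <- intercept + slope * bv[, h]
    pred <- matrix(NA_real_, m, m)
    pred[keep] <- pred_vec
    pred[t(keep)] <- t(pred)[t(keep)]
    pmask <- keep | t(keep)
    per_pair[[h]] <- sim_matrix(pred, pmask, kind = "predicted")
  }
  per_student <- lapply(seq_len(n_students), function(s) {
    take <- setdiff(which(pairs[, 1] == s | pairs[, 2] == s), skipped)
    if (!length(take)) return(NULL)
    acc <- Reduce(`+`, lapply(take, function(h) {
      v <- per_pair[[h]]$values
      v[!per_pair[[h]]$mask] <- 0
      v
    })) / length(take)
    mask <- per_pair[[take[1]]]$mask
    acc[!mask] <- NA_real_
    sim_matrix(acc, mask, kind = "predicted")
  })
  list(per_student = per_student, per_pair = per_pair, coef = coefs,
       skipped = skipped)
}

#' Similarity of a predicted matrix to a reference structure
#'
#' Spearman correlation between the predicted and reference matrices over
#' the intersection of their lower-triangle masks, converted to Fisher z
#' (clipped at `|rho| <= 1 - 1e-7`). Students contributing fewer than 3
#' jointly available cells (e.g. fewer than 3 recalled events) yield `NA`
#' with attribute `flagged`.
#'
#' @param predicted a predicted [sim_matrix()].
#' @param reference the reference [sim_matrix()] (original or recalled
#'   knowledge).
#' @return Fisher z (scalar).
#' @export
decode_similarity <- function(predicted, reference) {
  rho <- rsa_correlation(predicted, reference)
  if (!is.finite(rho)) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  fisher_z(rho)
}

#' One-sample group test on Fisher z values
#'
#' Standard one-sample t-test of the z values against zero, with Cohen's d
#' and the 95% confidence interval; zero-variance inputs are flagged as
#' degenerate.
#'
#' @param z numeric vector of Fisher z values (>= 3 finite).
#' @param mu null value (default 0).
#' @return list with `t`, `df`, `p`, `d`, `ci`, `n`, `mean`, `degenerate`.
#' @export
group_one_sample_test <- function(z, mu = 0) {
  one_sample_stats(z, mu = mu)
}

#' Decode knowledge structure from a cohort's brain activity
#'
#' End-to-end decoding for one channel: builds all pair brain matrices,
#' runs [loo_dyad_decode()], scores each student's predicted matrix against
#' a reference structure with [decode_similarity()], and tests the z values
#' against zero.
#'
#' @param x a cohort list or list of student [recording()]s.
#' @param event_set an [event_set()]; defaults to `x$event_set`.
#' @param knowledge knowledge [sim_matrix()] used as the regression target;
#'   defaults to `x$knowledge`.
#' @param channel channel index.
#' @param reference reference structure for scoring (defaults to
#'   `knowledge`; pass a recalled-knowledge matrix to score construction
#'   against what students actually recalled).
#' @param phase phase window.
#' @return an object of class `knowledge_decoding`.
#' @export
decode_knowledge <- function(x, event_set = NULL, knowledge = NULL, channel,
                             reference = NULL, phase = 1) {
  recs <- if (!is.null(x$students)) x$students else x
  event_set <- event_set %||% x$event_set
  knowledge <- as_sim(knowledge %||% x$knowledge %||%
                        cosine_knowledge_matrix(event_set), "knowledge")
  reference <- if (is.null(reference)) knowledge else
    as_sim(reference, "knowledge")
  sbm <- subject_brain_matrices(recs, event_set, channel, phase)
  dec <- loo_dyad_decode(sbm$pair_mats, knowledge, sbm$pairs,
                         n_students = length(recs))
  z <- vapply(dec$per_student, function(p) {
    if (is.null(p)) NA_real_ else decode_similarity(p, reference)
  }, numeric(1))
  rho <- tanh(z)
  tab <- data.frame(
    subject = vapply(recs, `[[`, character(1), "subject_id"),
    spearman = rho, z = z, stringsAsFactors = FALSE)
  structure(list(table = tab, group = group_one_sample_test(z),
                 decoding = dec, channel = channel,
                 n_pairs = nrow(sbm$pairs)),
            class = "knowledge_decoding")
}

#' @export
print.knowledge_decoding <- function(x, ...) {
  g <- x$group
  cat(sprintf("Leave-one-dyad-out decoding on channel %s (%d pairs, %d students)\n",
              x$channel, x$n_pairs, nrow(x$table)))
  cat(sprintf("  mean Spearman(predicted, reference) = %.3f\n",
              mean(x$table$spearman, na.rm = TRUE)))
  cat(sprintf("  one-sample t(%d) = %.3f, p = %.4g, Cohen's d = %.3f\n",
              g$df, g$t, g$p, g$d))
  invisible(x)
}

#' @export
summary.knowledge_decoding <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' @export
predict.knowledge_decoding <- function(object, ...) {
  object$decoding$per_student
}

#' Neural inter-subject pattern correlation (pISC)
#'
#' For each student, the Pearson correlation between the lower triangle of
#' their predicted knowledge matrix and that of every other student is
#' computed; the N - 1 coefficients are averaged and converted to Fisher z.
#' Constant matrices are flagged with `NA`.
#'
#' @param predicted list of predicted [sim_matrix()]s (one per student).
#' @return numeric vector of per-student pISC Fisher z values.
#' @export
neural_pisc <- function(predicted) {
  n <- length(predicted)
  if (n < 3) stop("need at least 3 students for pISC")
  pm <- lapply(predicted, function(x) as_sim(x, "predicted"))
  z <- vapply(seq_len(n), function(i) {
    rs <- vapply(setdiff(seq_len(n), i), function(j) {
      jl <- joint_lower(pm[[i]], pm[[j]])
      if (jl$n < 3 || sd(jl$a) < 1e-14 || sd(jl$b) < 1e-14) {
        return(NA_real_)
      }
      cor(jl$a, jl$b)
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    if (!length(rs)) NA_real_ else fisher_z(mean(rs))
  }, numeric(1))
  z
}

#' Jaccard similarity of two binary recall vectors
#'
#' `|intersection| / |union|` of the recalled-event sets; the similarity of
#' two empty vectors is defined as 0 (no shared recall signal).
#'
#' @param a,b logical or 0/1 vectors of common length.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
#' @examples
#' jaccard_similarity(c(1, 1, 0), c(1, 0, 1)) # 1/3
jaccard_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("recall vectors differ in length")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Behavioral inter-subject pattern correlation
#'
#' Per-student mean Jaccard similarity of the binary recall vector with all
#' other students' vectors. Pairs of empty vectors contribute 0 and are
#' flagged via the `empty_pairs` attribute.
#'
#' @param recall list of `recall_record`s (from [simulate_recall()]) or a
#'   students x events binary matrix.
#' @return numeric vector of per-student behavioral pISC values in
#'   `[0, 1]`.
#' @export
behavioral_pisc <- function(recall) {
  vecs <- if (is.matrix(recall)) {
    lapply(seq_len(nrow(recall)), function(i) as.logical(recall[i, ]))
  } else {
    lapply(recall, function(r) as.logical(if (is.list(r)) r$recalled else r))
  }
  n <- length(vecs)
  if (n < 2) stop("need at least 2 students")
  len <- unique(lengths(vecs))
  if (length(len) != 1) stop("recall vectors differ in length")
  empty <- 0L
  out <- vapply(seq_len(n), function(i) {
    js <- vapply(setdiff(seq_len(n), i), function(j) {
      if (!any(vecs[[i]]) && !any(vecs[[j]])) empty <<- empty + 1L
      jaccard_similarity(vecs[[i]], vecs[[j]])
    }, numeric(1))
    mean(js)
  }, numeric(1))
  attr(out, "empty_pairs") <- empty %/% 2L
  out
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after linear
#' removal of the covariates, with a one-tailed p-value on
#' `n - n_covariates - 2` degrees of freedom. With no covariates this is
#' the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector, matrix or data frame of
#'   covariates (e.g. age and socioeconomic status).
#' @param alternative `"greater"` (default, one-tailed positive, as used
#'   for brain-behavior coupling), `"less"` or `"two.sided"`.
#' @return list with `r`, `t`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- 0
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(cm) == n)
    k <- ncol(cm)
    design <- cbind(1, cm)
    if (qr(design)$rank < ncol(design)) {
      stop("collinear covariates")
    }
    x <- lm.fit(design, x)$residuals
    y <- lm.fit(design, y)$residuals
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  r <- cor(x, y)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, 1e-14))
  p <- switch(alternative,
              greater = pt(tval, df, lower.tail = FALSE),
              less = pt(tval, df),
              two.sided = 2 * pt(abs(tval), df, lower.tail = FALSE))
  list(r = r, t = tval, df = df, p = p)
}
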