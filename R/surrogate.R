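## Surrogate time series and the permutation p-value.

#' Phase-randomization surrogate
#'
#' Returns a surrogate series with the same amplitude spectrum (hence the
#' same autocorrelation) as the input but uniformly random Fourier phases.
#' DC and (for even lengths) the Nyquist bin are left untouched so the
#' output is real.
#'
#' @param x numeric series.
#' @return surrogate series of the same length.
#' @export
phase_randomize <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xf <- fft(x)
  half <- floor((n - 1) / 2)
  rot <- complex(modulus = 1, argument = runif(half, 0, 2 * pi))
  pos <- 2:(half + 1)
  xf[pos] <- xf[pos] * rot
  xf[n + 2 - pos] <- Conj(xf[pos])
  Re(fft(xf, inverse = TRUE)) / n
}

#' Time-point shuffling surrogate
#'
#' Randomly permutes the samples of the series, preserving the exact sample
#' multiset but destroying all temporal structure.
#'
#' @param x numeric series.
#' @return shuffled series.
#' @export
time_shuffle <- function(x) x[sample.int(length(x))]

#' Circular-shift surrogate
#'
#' Rotates the series left by `shift` samples (wrapping around), preserving
#' the exact sample multiset and all within-series structure except its
#' alignment. When `shift` is `NULL` a non-trivial shift is drawn uniformly
#' from `1..length(x) - 1`.
#'
#' @param x numeric series.
#' @param shift rotation in samples, or `NULL` for a random one.
#' @return rotated series.
#' @export
circular_shift <- function(x, shift = NULL) {
  n <- length(x)
  shift <- shift %||% sample.int(n - 1, 1)
  shift <- shift %% n
  if (shift == 0) return(x)
  c(x[(shift + 1):n], x[1:shift])
}

#' Apply a named surrogate transform
#'
#' @param x numeric series.
#' @param method one of `"phase_randomize"`, `"time_shuffle"`,
#'   `"circular_shift"`.
#' @param shift optional explicit shift for `"circular_shift"`.
#' @return surrogate series.
#' @export
surrogate_series <- function(x, method = c("phase_randomize",
                                           "time_shuffle",
                                           "circular_shift"),
                             shift = NULL) {
  method <- match.arg(method)
  switch(method,
         phase_randomize = phase_randomize(x),
         time_shuffle = time_shuffle(x),
         circular_shift = circular_shift(x, shift))
}

#' One-tailed permutation p-value
#'
#' Implements `p = (1 + #\{null >= empirical\}) / (1 + n_perm)`; by
#' construction p can never be 0 and is at most 1.
#'
#' @param observed empirical statistic.
#' @param null numeric vector of null statistics.
#' @return the p-value.
#' @export
#' @examples
#' permutation_pvalue(0.9, runif(99, 0, 0.5)) # 1/100
permutation_pvalue <- function(observed, null) {
  null <- null[is.finite(null)]
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Permutation null for a statistic of one series
#'
#' Generic single-series permutation engine: the statistic is evaluated on
#' the original series and on `n_perm` surrogates. For circular shifts the
#' surrogate shifts are drawn without replacement whenever `n_perm` does not
#' exceed the number of distinct non-trivial rotations, so that
#' `n_perm = length(x) - 1` (or `exhaustive = TRUE`) enumerates the null
#' exactly.
#'
#' @param x numeric series.
#' @param statistic function mapping a series to a scalar.
#' @param n_perm number of surrogates.
#' @param method surrogate type (see [surrogate_series()]).
#' @param seed integer seed.
#' @param exhaustive for `"circular_shift"`, use all `length(x) - 1`
#'   rotations.
#' @return list with `observed`, `null` and `p`.
#' @export
perm_null_series <- function(x, statistic, n_perm = 1000,
                             method = "phase_randomize", seed = NULL,
                             exhaustive = FALSE) {
  if (n_perm < 1 && !exhaustive) stop("n_perm must be at least 1")
  observed <- statistic(x)
  with_seed(seed, {
    null <- if (method == "circular_shift") {
      n <- length(x)
      shifts <- if (exhaustive || n_perm >= n - 1) {
        seq_len(n - 1)
      } else {
        sample(seq_len(n - 1), n_perm)
      }
      vapply(shifts, function(s) statistic(circular_shift(x, s)), numeric(1))
    } else {
      vapply(seq_len(n_perm),
             function(i) statistic(surrogate_series(x, method)), numeric(1))
    }
    list(observed = observed, null = null,
         p = permutation_pvalue(observed, null))
  })
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control across channels or grid cells.
#'
#' @param p vector of p-values in (0, 1].
#' @param q FDR threshold for the significance flags (default 0.05).
#' @return list with `q_values` (monotone BH-adjusted p-values) and
#'   `significant` (logical flags at `q_values < q`).
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (!length(p)) return(list(q_values = numeric(0), significant = logical(0)))
  qv <- p.adjust(p, method = "BH")
  list(q_values = qv, significant = is.finite(qv) & qv < q)
}
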