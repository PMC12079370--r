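## small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic per-stage fan-out of one master seed; stays below 2^31
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483629)
}

#' Fisher z transform with clipping
#'
#' Converts correlation coefficients to Fisher z, clipping the input to
#' `|r| <= 1 - 1e-7` so that perfect correlations stay finite.
#'
#' @param r numeric vector of correlations.
#' @param clip clipping bound applied to `|r|` before `atanh()`.
#' @return numeric vector of z values.
#' @export
#' @examples
#' fisher_z(0.5) # 0.5493
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

# strictly-lower-triangle values in column-major order
lower_vec <- function(m) m[lower.tri(m)]

# one-sample / paired t machinery shared by the group tests
one_sample_stats <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite values for a group test")
  s <- sd(x)
  if (s < 1e-12) {
    # zero-variance inputs: t is defined only when the mean is also 0
    if (abs(mean(x) - mu) < 1e-12) {
      return(list(t = 0, df = n - 1, p = 1, d = 0,
                  ci = c(mean(x), mean(x)), n = n, mean = mean(x),
                  degenerate = TRUE))
    }
    return(list(t = NA_real_, df = n - 1, p = NA_real_, d = NA_real_,
                ci = c(NA_real_, NA_real_), n = n, mean = mean(x),
                degenerate = TRUE))
  }
  tt <- t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(x) - mu) / s,
       ci = unname(tt$conf.int), n = n, mean = mean(x), degenerate = FALSE)
}
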