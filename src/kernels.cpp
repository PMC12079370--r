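// Inter-subject event-correlation kernels.
//
// Event series are stored as Lmax x M matrices, one column per event,
// zero-padded past each event's length. Correlations between events of
// unequal duration are computed over the first L = min(len_m, len_n)
// samples; with zero padding the cross dot-product over the full column
// already equals the truncated one, so each pair matrix costs one GEMM
// plus O(M^2) partial-sum lookups.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// partial sums of each column evaluated at every event length:
// PS(m, q) = sum of the first lens[q] samples of column m
static void partial_sums(const mat& E, const ivec& lens, mat& PS, mat& PSS) {
  const uword M = E.n_cols;
  PS.set_size(M, M);
  PSS.set_size(M, M);
  vec cs(E.n_rows), css(E.n_rows);
  for (uword m = 0; m < M; ++m) {
    double s = 0.0, ss = 0.0;
    for (uword t = 0; t < E.n_rows; ++t) {
      const double v = E(t, m);
      s += v; ss += v * v;
      cs(t) = s; css(t) = ss;
    }
    for (uword q = 0; q < M; ++q) {
      const uword L = (uword)lens(q);
      PS(m, q) = cs(L - 1);
      PSS(m, q) = css(L - 1);
    }
  }
}

// directed correlation matrix C(m, n) = cor(Ei[, m], Ej[, n]) over the
// first min(len_m, len_n) samples; NaN when L < 3 or a series is constant
static mat trunc_corr(const mat& Ei, const mat& Ej, const ivec& lens,
                      const mat& PSi, const mat& PSSi,
                      const mat& PSj, const mat& PSSj) {
  const uword M = Ei.n_cols;
  mat cross = Ei.t() * Ej;
  mat C(M, M);
  for (uword n = 0; n < M; ++n) {
    for (uword m = 0; m < M; ++m) {
      const uword q = (lens(m) <= lens(n)) ? m : n;
      const double L = (double)lens(q);
      if (L < 3) { C(m, n) = datum::nan; continue; }
      const double sx = PSi(m, q), sy = PSj(n, q);
      const double vx = L * PSSi(m, q) - sx * sx;
      const double vy = L * PSSj(n, q) - sy * sy;
      const double cxy = L * cross(m, n) - sx * sy;
      const double den = vx * vy;
      C(m, n) = (den > 0.0) ? cxy / std::sqrt(den) : datum::nan;
    }
  }
  return C;
}

// midranks (average ranks on ties), 1-based like R's rank()
static vec midrank(const vec& v) {
  const uword n = v.n_elem;
  uvec ord = sort_index(v);
  vec r(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && v(ord(j + 1)) == v(ord(i))) ++j;
    const double avg = 0.5 * (double)(i + j) + 1.0;
    for (uword k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  return r;
}

static double pearson(const vec& x, const vec& y) {
  const double n = (double)x.n_elem;
  const double sx = accu(x), sy = accu(y);
  const double vx = n * accu(x % x) - sx * sx;
  const double vy = n * accu(y % y) - sy * sy;
  const double cxy = n * accu(x % y) - sx * sy;
  const double den = vx * vy;
  return (den > 0.0) ? cxy / std::sqrt(den) : datum::nan;
}

// strictly-lower-triangle vector in R's column-major order
static vec lower_vec(const mat& A) {
  const uword M = A.n_rows;
  vec v(M * (M - 1) / 2);
  uword k = 0;
  for (uword n = 0; n < M; ++n)
    for (uword m = n + 1; m < M; ++m) v(k++) = A(m, n);
  return v;
}

// [[Rcpp::export]]
arma::mat cpp_pair_corr(const arma::mat& Ei, const arma::mat& Ej,
                        const arma::ivec& lens) {
  mat PSi, PSSi, PSj, PSSj;
  partial_sums(Ei, lens, PSi, PSSi);
  partial_sums(Ej, lens, PSj, PSSj);
  return trunc_corr(Ei, Ej, lens, PSi, PSSi, PSj, PSSj);
}

// all symmetrized pair matrices for a cohort, pairs ordered (1,2), (1,3),
// ..., (1,N), (2,3), ... to match t(combn(N, 2)) in R
// [[Rcpp::export]]
arma::cube cpp_all_pair_mats(const arma::cube& E, const arma::ivec& lens) {
  const uword N = E.n_slices, M = E.n_cols;
  std::vector<mat> PS(N), PSS(N);
  for (uword s = 0; s < N; ++s) partial_sums(E.slice(s), lens, PS[s], PSS[s]);
  cube out(M, M, N * (N - 1) / 2);
  uword g = 0;
  for (uword i = 0; i + 1 < N; ++i) {
    for (uword j = i + 1; j < N; ++j) {
      mat C = trunc_corr(E.slice(i), E.slice(j), lens, PS[i], PSS[i], PS[j], PSS[j]);
      out.slice(g++) = 0.5 * (C + C.t());
    }
  }
  return out;
}

// per-subject Spearman correlation between each subject's mean brain matrix
// (averaged over its N - 1 pairings) and pre-ranked knowledge values;
// kranks are midranks of the knowledge lower triangle in column-major order
// [[Rcpp::export]]
arma::vec cpp_cohort_rsa(const arma::cube& E, const arma::ivec& lens,
                         const arma::vec& kranks) {
  const uword N = E.n_slices, M = E.n_cols;
  std::vector<mat> PS(N), PSS(N);
  for (uword s = 0; s < N; ++s) partial_sums(E.slice(s), lens, PS[s], PSS[s]);
  cube acc(M, M, N, fill::zeros);
  for (uword i = 0; i + 1 < N; ++i) {
    for (uword j = i + 1; j < N; ++j) {
      mat C = trunc_corr(E.slice(i), E.slice(j), lens, PS[i], PSS[i], PS[j], PSS[j]);
      mat P = 0.5 * (C + C.t());
      acc.slice(i) += P;
      acc.slice(j) += P;
    }
  }
  vec r(N);
  for (uword s = 0; s < N; ++s) {
    vec b = lower_vec(acc.slice(s) / (double)(N - 1));
    uvec ok = find_finite(b);
    if (ok.n_elem < 3) { r(s) = datum::nan; continue; }
    if (ok.n_elem == b.n_elem) {
      r(s) = pearson(midrank(b), kranks);
    } else {
      vec bs = b(ok), ks = kranks(ok);
      r(s) = pearson(midrank(bs), midrank(ks));
    }
  }
  return r;
}

// mean over students of the symmetrized teacher-vs-student pair matrix
// [[Rcpp::export]]
arma::mat cpp_mean_pair_with(const arma::mat& Et, const arma::cube& Es,
                             const arma::ivec& lens) {
  const uword N = Es.n_slices, M = Et.n_cols;
  mat PSt, PSSt, PSs, PSSs;
  partial_sums(Et, lens, PSt, PSSt);
  mat acc(M, M, fill::zeros);
  for (uword s = 0; s < N; ++s) {
    partial_sums(Es.slice(s), lens, PSs, PSSs);
    mat C = trunc_corr(Et, Es.slice(s), lens, PSt, PSSt, PSs, PSSs);
    acc += 0.5 * (C + C.t());
  }
  return acc / (double)N;
}

// cohort-mean brain matrix = mean over all unordered pairs
// [[Rcpp::export]]
arma::mat cpp_mean_cohort_mat(const arma::cube& E, const arma::ivec& lens) {
  const uword N = E.n_slices, M = E.n_cols;
  std::vector<mat> PS(N), PSS(N);
  for (uword s = 0; s < N; ++s) partial_sums(E.slice(s), lens, PS[s], PSS[s]);
  mat acc(M, M, fill::zeros);
  uword g = 0;
  for (uword i = 0; i + 1 < N; ++i) {
    for (uword j = i + 1; j < N; ++j) {
      mat C = trunc_corr(E.slice(i), E.slice(j), lens, PS[i], PSS[i], PS[j], PSS[j]);
      acc += 0.5 * (C + C.t());
      ++g;
    }
  }
  return acc / (double)g;
}
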