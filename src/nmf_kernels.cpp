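// Core coordinate-descent and multiplicative NMF kernels.
//
// All kernels update the coefficient matrix H (k x m) of A ~ W H for fixed W;
// the basis update is obtained by the caller through transposition
// (A', H', W' with the alpha weights).  `beta = (b1, b2, b3)` are the weights
// of the ridge, angle (pairwise row inner product of H) and L1 penalties.
//
// Missing entries: `obs` is an n x m 0/1 pattern (empty => fully observed).
// Unobserved entries of A are never read.  Fixed entries: `fixed` is a
// k x m 0/1 pattern (empty => none); fixed coordinates are skipped, so they
// retain their incoming values bit-for-bit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int METHOD_SCD_MSE = 1;
static const int METHOD_LEE_MSE = 2;
static const int METHOD_SCD_KL  = 3;
static const int METHOD_LEE_KL  = 4;

// V = WtW + b1 I + b2 (E - I) for a precomputed Gram matrix.
static mat penalized_gram(const mat& gram, double b1, double b2) {
  mat V = gram + b2;
  V.diag() += b1 - b2;
  return V;
}

// Cyclic coordinate descent sweeps on 1/2 h'Vh + u'h, h >= 0, one column.
// g must hold V h + u on entry and is kept consistent.  Returns number of
// sweeps actually run (early exit when a sweep changes nothing).
static int scd_sweeps_col(const mat& V, vec& g, vec& h,
                          const uvec& fixed_col, bool any_fixed,
                          int n_inner, double eps) {
  const uword k = h.n_elem;
  int sweeps = 0;
  for (int t = 0; t < n_inner; ++t) {
    bool changed = false;
    for (uword kk = 0; kk < k; ++kk) {
      if (any_fixed && fixed_col(kk)) continue;
      double vkk = V(kk, kk);
      if (vkk <= 0) vkk = eps;
      double h0 = h(kk);
      double h1 = h0 - g(kk) / vkk;
      if (h1 < 0) h1 = 0;
      if (h1 != h0) {
        g += (h1 - h0) * V.col(kk);
        h(kk) = h1;
        changed = true;
      }
    }
    ++sweeps;
    if (!changed) break;
  }
  return sweeps;
}

// Sequential quadratic (Newton-like) KL sweeps for one column.
// a_col holds the observed entries of A's column, rows of W restricted
// likewise; wh = W_obs h is maintained incrementally.
static void kl_sweeps_col(const mat& Wobs, const vec& a_col, vec& h, vec& wh,
                          const uvec& fixed_col, bool any_fixed,
                          double b1, double b2, double b3,
                          int n_inner, double eps) {
  const uword k = h.n_elem;
  const uword nobs = a_col.n_elem;
  for (int t = 0; t < n_inner; ++t) {
    for (uword kk = 0; kk < k; ++kk) {
      if (any_fixed && fixed_col(kk)) continue;
      double b = 0.0, a = 0.0;
      for (uword l = 0; l < nobs; ++l) {
        const double w = Wobs(l, kk);
        if (w == 0.0 && a_col(l) == 0.0) continue;
        const double d = wh(l) + eps;
        const double r = w / d;
        b += w - a_col(l) * r;
        a += a_col(l) * r * r;
      }
      const double cross = accu(h) - h(kk);
      double den = a + b1;
      if (den <= 0) den = eps;
      double h1 = (a * h(kk) - b - b2 * cross - b3) / den;
      if (h1 < 0) h1 = 0;
      if (h1 != h(kk)) {
        wh += (h1 - h(kk)) * Wobs.col(kk);
        h(kk) = h1;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List c_scd_quad(const arma::mat& V, const arma::mat& U,
                      arma::mat H, int n_inner, double eps) {
  const uword m = H.n_cols;
  mat G = V * H + U;
  uvec no_fixed;
  int max_sweeps = 0;
  for (uword j = 0; j < m; ++j) {
    vec g = G.col(j), h = H.col(j);
    int s = scd_sweeps_col(V, g, h, no_fixed, false, n_inner, eps);
    H.col(j) = h;
    if (s > max_sweeps) max_sweeps = s;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("sweeps") = max_sweeps);
}

// [[Rcpp::export]]
arma::mat c_update_factor(const arma::mat& A, const arma::mat& W, arma::mat H,
                          const arma::vec& beta, const arma::umat& obs,
                          const arma::umat& fixed, int n_inner, double eps,
                          int method) {
  const uword k = W.n_cols;
  const uword m = H.n_cols;
  const bool missing = obs.n_elem > 0;
  const bool any_fixed = fixed.n_elem > 0;
  const double b1 = beta(0), b2 = beta(1), b3 = beta(2);
  uvec no_fixed;

  if (method == METHOD_SCD_MSE) {
    if (!missing) {
      const mat V = penalized_gram(W.t() * W, b1, b2);
      mat G = V * H + (-W.t() * A + b3);
      for (uword j = 0; j < m; ++j) {
        vec g = G.col(j), h = H.col(j);
        uvec fcol = any_fixed ? fixed.col(j) : no_fixed;
        scd_sweeps_col(V, g, h, fcol, any_fixed, n_inner, eps);
        H.col(j) = h;
      }
    } else {
      for (uword j = 0; j < m; ++j) {
        const uvec I = find(obs.col(j));
        if (I.n_elem == 0) Rcpp::stop("column with no observed entries");
        const mat WI = W.rows(I);
        const mat V = penalized_gram(WI.t() * WI, b1, b2);
        const vec u = -WI.t() * A.submat(I, uvec{j}) + b3;
        vec h = H.col(j);
        vec g = V * h + u;
        uvec fcol = any_fixed ? fixed.col(j) : no_fixed;
        scd_sweeps_col(V, g, h, fcol, any_fixed, n_inner, eps);
        H.col(j) = h;
      }
    }
  } else if (method == METHOD_LEE_MSE) {
    if (!missing) {
      const mat V = penalized_gram(W.t() * W, b1, b2);
      const mat WtA = W.t() * A;
      for (int t = 0; t < n_inner; ++t) {
        const mat D = V * H + b3;
        for (uword j = 0; j < m; ++j) {
          for (uword kk = 0; kk < k; ++kk) {
            if (any_fixed && fixed(kk, j)) continue;
            H(kk, j) *= WtA(kk, j) / (D(kk, j) + eps);
          }
        }
      }
    } else {
      for (uword j = 0; j < m; ++j) {
        const uvec I = find(obs.col(j));
        if (I.n_elem == 0) Rcpp::stop("column with no observed entries");
        const mat WI = W.rows(I);
        const mat V = penalized_gram(WI.t() * WI, b1, b2);
        const vec wta = WI.t() * A.submat(I, uvec{j});
        vec h = H.col(j);
        for (int t = 0; t < n_inner; ++t) {
          const vec d = V * h + b3;
          for (uword kk = 0; kk < k; ++kk) {
            if (any_fixed && fixed(kk, j)) continue;
            h(kk) *= wta(kk) / (d(kk) + eps);
          }
        }
        H.col(j) = h;
      }
    }
  } else if (method == METHOD_SCD_KL) {
    for (uword j = 0; j < m; ++j) {
      vec h = H.col(j);
      uvec fcol = any_fixed ? fixed.col(j) : no_fixed;
      if (!missing) {
        const vec a_col = A.col(j);
        vec wh = W * h;
        kl_sweeps_col(W, a_col, h, wh, fcol, any_fixed,
                      b1, b2, b3, n_inner, eps);
      } else {
        const uvec I = find(obs.col(j));
        if (I.n_elem == 0) Rcpp::stop("column with no observed entries");
        const mat WI = W.rows(I);
        const vec a_col = A.submat(I, uvec{j});
        vec wh = WI * h;
        kl_sweeps_col(WI, a_col, h, wh, fcol, any_fixed,
                      b1, b2, b3, n_inner, eps);
      }
      H.col(j) = h;
    }
  } else if (method == METHOD_LEE_KL) {
    for (uword j = 0; j < m; ++j) {
      uvec I;
      if (missing) {
        I = find(obs.col(j));
        if (I.n_elem == 0) Rcpp::stop("column with no observed entries");
      }
      const mat WI = missing ? mat(W.rows(I)) : W;
      const vec a_col = missing ? vec(A.submat(I, uvec{j})) : vec(A.col(j));
      const rowvec wsum = sum(WI, 0);
      vec h = H.col(j);
      vec hn = h;
      for (int t = 0; t < n_inner; ++t) {
        const vec wh = WI * h;
        const double colsum = accu(h);
        for (uword kk = 0; kk < k; ++kk) {
          if (any_fixed && fixed(kk, j)) continue;
          double num = 0.0;
          for (uword l = 0; l < a_col.n_elem; ++l) {
            if (a_col(l) == 0.0) continue;
            num += WI(l, kk) * a_col(l) / (wh(l) + eps);
          }
          const double den = wsum(kk) + (b1 - b2) * h(kk)
                             + b2 * colsum + b3;
          hn(kk) = h(kk) * num / (den + eps);
        }
        h = hn;
      }
      H.col(j) = h;
    }
  } else {
    Rcpp::stop("unknown method code");
  }
  return H;
}
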