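// Compiled kernels: weighted alignment statistics, Potts-model Gibbs
// sampling, pseudolikelihood objective/gradient, graphical lasso
// coordinate descent, and a small deterministic multilayer perceptron.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Weighted single-site and pairwise state counts.
// msa: N x L integers in 1..q (q includes the gap state); w: per-sequence
// weights. Returns raw weighted counts; pseudocounts and normalization are
// applied in R. c2 is the (L*q) x (L*q) symmetric block matrix whose (i,j)
// block holds pair counts; diagonal blocks are diag(c1[, i]).
// [[Rcpp::export]]
List freq_counts_cpp(const arma::imat& msa, const arma::vec& w, int q) {
  const int N = msa.n_rows, L = msa.n_cols;
  arma::mat c1(q, L, arma::fill::zeros);
  arma::mat c2(L * q, L * q, arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    const double ws = w[s];
    for (int i = 0; i < L; ++i) {
      const int a = msa(s, i) - 1;
      c1(a, i) += ws;
      for (int j = i + 1; j < L; ++j) {
        const int b = msa(s, j) - 1;
        c2(i * q + a, j * q + b) += ws;
      }
    }
  }
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < q; ++a)
      c2(i * q + a, i * q + a) = c1(a, i);
  c2 = arma::symmatu(c2);
  return List::create(_["c1"] = c1, _["c2"] = c2);
}

// ---------------------------------------------------------------------------
// Pairwise sequence identity: matches / (columns where at least one of the
// two sequences is non-gap). gap_state is the integer code of the gap.
// [[Rcpp::export]]
arma::mat identity_matrix_cpp(const arma::imat& msa, int gap_state) {
  const int N = msa.n_rows, L = msa.n_cols;
  arma::mat id(N, N, arma::fill::ones);
  for (int s = 0; s < N; ++s) {
    for (int t = s + 1; t < N; ++t) {
      int match = 0, denom = 0;
      for (int i = 0; i < L; ++i) {
        const int a = msa(s, i), b = msa(t, i);
        if (a == gap_state && b == gap_state) continue;
        ++denom;
        if (a == b) ++match;
      }
      const double v = denom > 0 ? double(match) / denom : 0.0;
      id(s, t) = v;
      id(t, s) = v;
    }
  }
  return id;
}

// ---------------------------------------------------------------------------
// Single-site Gibbs sampler for a Potts model. h: q x L fields; Jm: the
// (L*q) x (L*q) full symmetric coupling matrix (block (i,j) = J_ij(a,b)).
// Uses the R RNG so set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(const arma::mat& h, const arma::mat& Jm,
                               int n_keep, int burn_in, int thinning) {
  const int q = h.n_rows, L = h.n_cols;
  IntegerMatrix out(n_keep, L);
  arma::ivec x(L);
  arma::vec e(q), p(q);

  // initialize from the single-site field distributions
  for (int i = 0; i < L; ++i) {
    arma::vec pi = arma::exp(h.col(i) - h.col(i).max());
    pi /= arma::accu(pi);
    double u = R::unif_rand(), acc = 0.0;
    int a = q - 1;
    for (int k = 0; k < q; ++k) { acc += pi[k]; if (u <= acc) { a = k; break; } }
    x[i] = a;
  }

  const int total = burn_in + n_keep * thinning;
  int kept = 0;
  for (int sweep = 1; sweep <= total; ++sweep) {
    for (int i = 0; i < L; ++i) {
      e = h.col(i);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        e += Jm(arma::span(i * q, i * q + q - 1),
                arma::span(j * q + x[j], j * q + x[j]));
      }
      p = arma::exp(e - e.max());
      p /= arma::accu(p);
      double u = R::unif_rand(), acc = 0.0;
      int a = q - 1;
      for (int k = 0; k < q; ++k) { acc += p[k]; if (u <= acc) { a = k; break; } }
      x[i] = a;
    }
    if (sweep > burn_in && (sweep - burn_in) % thinning == 0) {
      for (int i = 0; i < L; ++i) out(kept, i) = x[i] + 1;
      ++kept;
      if (kept == n_keep) break;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Negative weighted L2-regularized log-pseudolikelihood and its gradient.
// Parameter vector: h (q*L, site-major) followed by one q*q block per pair
// (i<j) in row-scan order, J_ij(a,b) stored with a fastest.
// [[Rcpp::export]]
List plm_obj_grad_cpp(const arma::vec& par, const arma::imat& msa,
                      const arma::vec& w, int q, double l2_field,
                      double l2_coupling) {
  const int N = msa.n_rows, L = msa.n_cols;
  const int nh = q * L;
  arma::vec grad(par.n_elem, arma::fill::zeros);
  double obj = 0.0;

  // pair block offsets
  arma::imat poff(L, L, arma::fill::zeros);
  {
    int off = nh;
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j) { poff(i, j) = off; off += q * q; }
  }

  arma::mat z(q, L), resid(q, L);
  for (int s = 0; s < N; ++s) {
    const double ws = w[s];
    // logits for every site's conditional
    for (int i = 0; i < L; ++i)
      z.col(i) = par.subvec(i * q, i * q + q - 1);
    for (int i = 0; i < L; ++i) {
      const int xi = msa(s, i) - 1;
      for (int j = i + 1; j < L; ++j) {
        const int xj = msa(s, j) - 1;
        const int off = poff(i, j);
        // J_ij(., x_j) enters site i's conditional
        z.col(i) += par.subvec(off + xj * q, off + xj * q + q - 1);
        // J_ij(x_i, .) enters site j's conditional
        for (int b = 0; b < q; ++b) z(b, j) += par[off + b * q + xi];
      }
    }
    for (int i = 0; i < L; ++i) {
      const int xi = msa(s, i) - 1;
      const double m = z.col(i).max();
      arma::vec ez = arma::exp(z.col(i) - m);
      const double Z = arma::accu(ez);
      obj -= ws * (z(xi, i) - m - std::log(Z));
      resid.col(i) = ws * (ez / Z);
      resid(xi, i) -= ws;
    }
    for (int i = 0; i < L; ++i) {
      grad.subvec(i * q, i * q + q - 1) += resid.col(i);
      const int xi = msa(s, i) - 1;
      for (int j = i + 1; j < L; ++j) {
        const int xj = msa(s, j) - 1;
        const int off = poff(i, j);
        grad.subvec(off + xj * q, off + xj * q + q - 1) += resid.col(i);
        for (int b = 0; b < q; ++b) grad[off + b * q + xi] += resid(b, j);
      }
    }
  }

  // L2 penalties
  const arma::vec hpart = par.subvec(0, nh - 1);
  const arma::vec Jpart = par.subvec(nh, par.n_elem - 1);
  obj += l2_field * arma::dot(hpart, hpart) + l2_coupling * arma::dot(Jpart, Jpart);
  grad.subvec(0, nh - 1) += 2.0 * l2_field * hpart;
  grad.subvec(nh, par.n_elem - 1) += 2.0 * l2_coupling * Jpart;

  return List::create(_["obj"] = obj, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// Graphical lasso by block coordinate descent (Friedman et al. style):
// maximizes log det Theta - tr(S Theta) - rho * ||Theta||_1.
// Returns the precision matrix, the estimated covariance W, the objective
// trace over sweeps, and a convergence flag.
// [[Rcpp::export]]
List glasso_cpp(const arma::mat& S, double rho, double tol, int max_iter,
                bool track_obj = false) {
  const int p = S.n_rows;
  arma::mat W = S;
  W.diag() += rho;
  arma::mat B(p, p, arma::fill::zeros);  // column j: lasso coefficients
  double offmean = arma::accu(arma::abs(S)) / (double(p) * p);
  if (offmean <= 0) offmean = 1.0;

  // recover the precision matrix from the current (W, B) state
  auto recover_theta = [&](void) {
    arma::mat Th(p, p, arma::fill::zeros);
    for (int j = 0; j < p; ++j) {
      arma::vec beta = B.col(j);
      beta[j] = 0.0;
      const double denom = W(j, j) - arma::dot(arma::vec(W * beta), beta);
      const double t22 = 1.0 / denom;
      Th(j, j) = t22;
      for (int k = 0; k < p; ++k)
        if (k != j) Th(k, j) = -beta[k] * t22;
    }
    return arma::mat(0.5 * (Th + Th.t()));
  };

  bool converged = false;
  int sweep = 0;
  std::vector<double> objtrace, maxdiffs;
  for (sweep = 1; sweep <= max_iter; ++sweep) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::vec beta = B.col(j);
      beta[j] = 0.0;
      arma::vec u = W * beta;  // includes row j, harmless (beta_j = 0)
      // coordinate descent on the dual lasso for column j
      for (int inner = 0; inner < 50; ++inner) {
        double del = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          const double wkk = W(k, k);
          const double r = S(k, j) - (u[k] - wkk * beta[k]);
          double bnew = 0.0;
          if (r > rho) bnew = (r - rho) / wkk;
          else if (r < -rho) bnew = (r + rho) / wkk;
          const double d = bnew - beta[k];
          if (d != 0.0) {
            u += d * W.col(k);
            beta[k] = bnew;
            del = std::max(del, std::abs(d));
          }
        }
        if (del < tol * 0.1) break;
      }
      B.col(j) = beta;
      arma::vec w12 = W * beta;
      w12[j] = W(j, j);
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        maxdiff = std::max(maxdiff, std::abs(W(k, j) - w12[k]));
        W(k, j) = w12[k];
        W(j, k) = w12[k];
      }
    }
    maxdiffs.push_back(maxdiff);
    if (track_obj) {
      // penalized log-likelihood: log det Theta - tr(S Theta) - rho ||Theta||_1
      arma::mat Th = recover_theta();
      double ld, sgn;
      bool ok = arma::log_det(ld, sgn, Th);
      objtrace.push_back(ok && sgn > 0
        ? ld - arma::trace(S * Th) - rho * arma::accu(arma::abs(Th))
        : NA_REAL);
    }
    if (maxdiff < tol * offmean) { converged = true; break; }
  }

  arma::mat Theta = recover_theta();

  return List::create(_["theta"] = Theta, _["w"] = W,
                      _["sweeps"] = sweep, _["converged"] = converged,
                      _["trace"] = maxdiffs, _["obj_trace"] = objtrace);
}

// ---------------------------------------------------------------------------
// Deterministic one-hidden-layer MLP (logistic hidden and output), trained
// by mini-batch Adam on weighted cross-entropy. All randomness (init and
// per-epoch shuffling) comes from an internal xorshift generator seeded by
// `seed`, so identical calls give bitwise-identical weights.
namespace {
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return int(next() % uint64_t(n)); }
};
inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y, const arma::vec& sw,
                   int hidden, int epochs, double lr, int batch, double l2,
                   int seed) {
  const int n = X.n_rows, d = X.n_cols;
  XorShift rng(uint64_t(seed) * 2862933555777941757ULL + 3037000493ULL);

  const double r1 = std::sqrt(6.0 / (d + hidden));
  const double r2 = std::sqrt(6.0 / (hidden + 1));
  arma::mat W1(d, hidden);
  arma::vec b1(hidden, arma::fill::zeros), w2(hidden);
  double b2 = 0.0;
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < hidden; ++j) W1(i, j) = (2.0 * rng.unif() - 1.0) * r1;
  for (int j = 0; j < hidden; ++j) w2[j] = (2.0 * rng.unif() - 1.0) * r2;

  // Adam state
  arma::mat mW1(d, hidden, arma::fill::zeros), vW1(d, hidden, arma::fill::zeros);
  arma::vec mb1(hidden, arma::fill::zeros), vb1(hidden, arma::fill::zeros);
  arma::vec mw2(hidden, arma::fill::zeros), vw2(hidden, arma::fill::zeros);
  double mb2 = 0.0, vb2 = 0.0;
  const double be1 = 0.9, be2 = 0.999, eps = 1e-8;
  long t = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  const double wsum = arma::accu(sw);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) std::swap(idx[i], idx[rng.below(i + 1)]);
    for (int start = 0; start < n; start += batch) {
      const int end = std::min(start + batch, n);
      const int m = end - start;
      arma::uvec rows(m);
      for (int k = 0; k < m; ++k) rows[k] = idx[start + k];
      arma::mat Xb = X.rows(rows);
      arma::vec yb = y.elem(rows), swb = sw.elem(rows);

      arma::mat A1 = sigm(Xb * W1 + arma::repmat(b1.t(), m, 1));
      arma::vec pb = 1.0 / (1.0 + arma::exp(-(A1 * w2 + b2)));
      arma::vec d2 = swb % (pb - yb) * (double(n) / (wsum * m));
      arma::vec gw2 = A1.t() * d2 + l2 * w2;
      const double gb2 = arma::accu(d2);
      arma::mat D1 = (d2 * w2.t()) % A1 % (1.0 - A1);
      arma::mat gW1 = Xb.t() * D1 + l2 * W1;
      arma::vec gb1 = arma::sum(D1, 0).t();

      ++t;
      const double c1 = 1.0 - std::pow(be1, double(t));
      const double c2 = 1.0 - std::pow(be2, double(t));
      mW1 = be1 * mW1 + (1 - be1) * gW1; vW1 = be2 * vW1 + (1 - be2) * (gW1 % gW1);
      W1 -= lr * (mW1 / c1) / (arma::sqrt(vW1 / c2) + eps);
      mb1 = be1 * mb1 + (1 - be1) * gb1; vb1 = be2 * vb1 + (1 - be2) * (gb1 % gb1);
      b1 -= lr * (mb1 / c1) / (arma::sqrt(vb1 / c2) + eps);
      mw2 = be1 * mw2 + (1 - be1) * gw2; vw2 = be2 * vw2 + (1 - be2) * (gw2 % gw2);
      w2 -= lr * (mw2 / c1) / (arma::sqrt(vw2 / c2) + eps);
      mb2 = be1 * mb2 + (1 - be1) * gb2; vb2 = be2 * vb2 + (1 - be2) * gb2 * gb2;
      b2 -= lr * (mb2 / c1) / (std::sqrt(vb2 / c2) + eps);
    }
  }

  return List::create(_["W1"] = W1, _["b1"] = b1, _["w2"] = w2, _["b2"] = b2);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat& W1, const arma::vec& b1,
                          const arma::vec& w2, double b2, const arma::mat& X) {
  const int m = X.n_rows;
  arma::mat A1 = sigm(X * W1 + arma::repmat(b1.t(), m, 1));
  return 1.0 / (1.0 + arma::exp(-(A1 * w2 + b2)));
}
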