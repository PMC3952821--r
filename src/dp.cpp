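// Banded dynamic programming over the (stimulus x response x state)
// alignment tensor: generalized forward, backward, Viterbi, and expected
// transition counts for EM.  All arithmetic in the log domain.
//
// Conventions (shared with the R wrappers in R/dp.R):
//  - kinds: 0 = X (consumes stimulus symbol), 1 = R (consumes response
//    symbol), 2 = M (consumes one of each).
//  - Cell (i, j) means i stimulus symbols and j response symbols consumed;
//    i runs 0..Tx, j runs 0..Tr, restricted to |i - j| <= W.
//  - Banded storage: cube(i, j - i + W, s); the middle index runs 0..2W.
//  - Emission inputs are precomputed in R:
//      EX: Tx x N, log e_s(x_i) for X-state columns;
//      ER: Tr x N, log e_s(r_j) for R-state columns;
//      EM: Tx x V x N cube, log e_s(x_i, v) for M-state slices
//          (marginal response probability already folded in);
//      r:  integer response symbols, 0-based values in 0..V-1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Band {
  int Tx, Tr, W;
  bool inside(int i, int j) const {
    return i >= 0 && i <= Tx && j >= 0 && j <= Tr && std::abs(i - j) <= W;
  }
  int col(int i, int j) const { return j - i + W; }
};

static inline double lse_acc(double acc, double x) {
  // running log-sum-exp of two terms
  if (x == NEG_INF) return acc;
  if (acc == NEG_INF) return x;
  if (acc > x) return acc + std::log1p(std::exp(x - acc));
  return x + std::log1p(std::exp(acc - x));
}

// emission log-probability of state s consuming into cell (i, j)
static inline double emit_into(int kind, int s, int i, int j,
                               const arma::mat& EX, const arma::mat& ER,
                               const arma::cube& EM, const IntegerVector& r) {
  if (kind == 0) return EX(i - 1, s);
  if (kind == 1) return ER(j - 1, s);
  return EM(i - 1, r[j - 1], s);
}

// Per-state lag bounds (lag = j - i): a state may only occupy cells whose
// lag lies in [lag_lo[s], lag_hi[s]].  For plain models these are -W..W for
// every state; the inference rewriting uses them to let the intermediate
// stimulus-halves of split M-states transiently exceed the band by one.

// [[Rcpp::export]]
List dp_forward_cpp(IntegerVector kinds, arma::mat logA, arma::vec logrho,
                    arma::vec logtau, int Tx, int Tr, int W,
                    arma::mat EX, arma::mat ER, arma::cube EM,
                    IntegerVector r, IntegerVector lag_lo,
                    IntegerVector lag_hi) {
  int N = kinds.size();
  Band b{Tx, Tr, W};
  arma::cube alpha(Tx + 1, 2 * W + 1, N);
  alpha.fill(NEG_INF);

  for (int i = 0; i <= Tx; ++i) {
    int jlo = std::max(0, i - W), jhi = std::min(Tr, i + W);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) continue;
      for (int s = 0; s < N; ++s) {
        if (j - i < lag_lo[s] || j - i > lag_hi[s]) continue;
        int k = kinds[s];
        int pi = (k == 1) ? i : i - 1;
        int pj = (k == 0) ? j : j - 1;
        if (pi < 0 || pj < 0) continue;
        double acc;
        if (pi == 0 && pj == 0) {
          acc = logrho[s];
        } else {
          if (!b.inside(pi, pj)) continue;
          acc = NEG_INF;
          for (int sp = 0; sp < N; ++sp)
            acc = lse_acc(acc, alpha(pi, b.col(pi, pj), sp) + logA(sp, s));
        }
        if (acc == NEG_INF) continue;
        alpha(i, b.col(i, j), s) = emit_into(k, s, i, j, EX, ER, EM, r) + acc;
      }
    }
  }

  double ll = NEG_INF;
  if (b.inside(Tx, Tr))
    for (int s = 0; s < N; ++s)
      ll = lse_acc(ll, alpha(Tx, b.col(Tx, Tr), s) + logtau[s]);
  return List::create(_["alpha"] = alpha, _["loglik"] = ll);
}

// [[Rcpp::export]]
List dp_backward_cpp(IntegerVector kinds, arma::mat logA, arma::vec logrho,
                     arma::vec logtau, int Tx, int Tr, int W,
                     arma::mat EX, arma::mat ER, arma::cube EM,
                     IntegerVector r, IntegerVector lag_lo,
                     IntegerVector lag_hi) {
  int N = kinds.size();
  Band b{Tx, Tr, W};
  arma::cube beta(Tx + 1, 2 * W + 1, N);
  beta.fill(NEG_INF);
  if (b.inside(Tx, Tr))
    for (int s = 0; s < N; ++s) beta(Tx, b.col(Tx, Tr), s) = logtau[s];

  for (int i = Tx; i >= 0; --i) {
    int jlo = std::max(0, i - W), jhi = std::min(Tr, i + W);
    for (int j = jhi; j >= jlo; --j) {
      if (i == Tx && j == Tr) continue;
      for (int s = 0; s < N; ++s) {
        double acc = NEG_INF;
        for (int sp = 0; sp < N; ++sp) {
          int k = kinds[sp];
          int ni = (k == 1) ? i : i + 1;
          int nj = (k == 0) ? j : j + 1;
          if (ni > Tx || nj > Tr || !b.inside(ni, nj)) continue;
          if (nj - ni < lag_lo[sp] || nj - ni > lag_hi[sp]) continue;
          double e = emit_into(k, sp, ni, nj, EX, ER, EM, r);
          acc = lse_acc(acc, logA(s, sp) + e + beta(ni, b.col(ni, nj), sp));
        }
        beta(i, b.col(i, j), s) = acc;
      }
    }
  }

  // total probability via the start distribution (consistency check)
  double ll = NEG_INF;
  for (int s = 0; s < N; ++s) {
    int k = kinds[s];
    int ni = (k == 1) ? 0 : 1;
    int nj = (k == 0) ? 0 : 1;
    if (ni > Tx || nj > Tr || !b.inside(ni, nj)) continue;
    if (nj - ni < lag_lo[s] || nj - ni > lag_hi[s]) continue;
    double e = emit_into(k, s, ni, nj, EX, ER, EM, r);
    ll = lse_acc(ll, logrho[s] + e + beta(ni, b.col(ni, nj), s));
  }
  return List::create(_["beta"] = beta, _["loglik"] = ll);
}

// [[Rcpp::export]]
List dp_viterbi_cpp(IntegerVector kinds, arma::mat logA, arma::vec logrho,
                    arma::vec logtau, int Tx, int Tr, int W,
                    arma::mat EX, arma::mat ER, arma::cube EM,
                    IntegerVector r, IntegerVector lag_lo,
                    IntegerVector lag_hi) {
  int N = kinds.size();
  Band b{Tx, Tr, W};
  arma::cube delta(Tx + 1, 2 * W + 1, N);
  delta.fill(NEG_INF);
  arma::icube ptr(Tx + 1, 2 * W + 1, N);
  ptr.fill(-2);  // -2 unreachable, -1 start

  for (int i = 0; i <= Tx; ++i) {
    int jlo = std::max(0, i - W), jhi = std::min(Tr, i + W);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) continue;
      for (int s = 0; s < N; ++s) {
        if (j - i < lag_lo[s] || j - i > lag_hi[s]) continue;
        int k = kinds[s];
        int pi = (k == 1) ? i : i - 1;
        int pj = (k == 0) ? j : j - 1;
        if (pi < 0 || pj < 0) continue;
        double best;
        int arg;
        if (pi == 0 && pj == 0) {
          best = logrho[s];
          arg = -1;
        } else {
          if (!b.inside(pi, pj)) continue;
          best = NEG_INF;
          arg = -2;
          for (int sp = 0; sp < N; ++sp) {
            double v = delta(pi, b.col(pi, pj), sp) + logA(sp, s);
            if (v > best) { best = v; arg = sp; }  // ties: lowest index wins
          }
        }
        if (best == NEG_INF) continue;
        delta(i, b.col(i, j), s) =
            emit_into(k, s, i, j, EX, ER, EM, r) + best;
        ptr(i, b.col(i, j), s) = arg;
      }
    }
  }

  double best = NEG_INF;
  int arg = -1;
  if (b.inside(Tx, Tr)) {
    // final-state tie preference: M over X over R, then lowest index
    std::vector<int> order(N);
    for (int s = 0; s < N; ++s) order[s] = s;
    std::stable_sort(order.begin(), order.end(), [&](int a2, int b2) {
      int pa = (kinds[a2] == 2) ? 0 : (kinds[a2] == 0 ? 1 : 2);
      int pb = (kinds[b2] == 2) ? 0 : (kinds[b2] == 0 ? 1 : 2);
      return pa < pb;
    });
    for (int s : order) {
      double v = delta(Tx, b.col(Tx, Tr), s) + logtau[s];
      if (v > best) { best = v; arg = s; }
    }
  }
  return List::create(_["delta"] = delta, _["ptr"] = ptr,
                      _["logp"] = best, _["final_state"] = arg + 1);
}

// Expected transition counts, start and terminal occupancies for EM.
// [[Rcpp::export]]
List dp_xi_cpp(IntegerVector kinds, arma::mat logA, arma::vec logrho,
               arma::vec logtau, int Tx, int Tr, int W,
               arma::mat EX, arma::mat ER, arma::cube EM, IntegerVector r,
               IntegerVector lag_lo, IntegerVector lag_hi,
               arma::cube alpha, arma::cube beta, double loglik) {
  int N = kinds.size();
  Band b{Tx, Tr, W};
  arma::mat xi(N, N, arma::fill::zeros);
  arma::vec init_occ(N, arma::fill::zeros), final_occ(N, arma::fill::zeros);

  for (int i = 0; i <= Tx; ++i) {
    int jlo = std::max(0, i - W), jhi = std::min(Tr, i + W);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) continue;
      for (int s = 0; s < N; ++s) {
        double a = alpha(i, b.col(i, j), s);
        if (a == NEG_INF) continue;
        for (int sp = 0; sp < N; ++sp) {
          int k = kinds[sp];
          int ni = (k == 1) ? i : i + 1;
          int nj = (k == 0) ? j : j + 1;
          if (ni > Tx || nj > Tr || !b.inside(ni, nj)) continue;
          if (nj - ni < lag_lo[sp] || nj - ni > lag_hi[sp]) continue;
          double e = emit_into(k, sp, ni, nj, EX, ER, EM, r);
          double v = a + logA(s, sp) + e + beta(ni, b.col(ni, nj), sp) - loglik;
          if (v != NEG_INF) xi(s, sp) += std::exp(v);
        }
      }
    }
  }
  for (int s = 0; s < N; ++s) {
    int k = kinds[s];
    int ni = (k == 1) ? 0 : 1;
    int nj = (k == 0) ? 0 : 1;
    if (ni <= Tx && nj <= Tr && b.inside(ni, nj) &&
        nj - ni >= lag_lo[s] && nj - ni <= lag_hi[s]) {
      double e = emit_into(k, s, ni, nj, EX, ER, EM, r);
      double v = logrho[s] + e + beta(ni, b.col(ni, nj), s) - loglik;
      if (v != NEG_INF) init_occ[s] = std::exp(v);
    }
    if (b.inside(Tx, Tr)) {
      double v = alpha(Tx, b.col(Tx, Tr), s) + logtau[s] - loglik;
      if (v != NEG_INF) final_occ[s] = std::exp(v);
    }
  }
  return List::create(_["xi"] = xi, _["init_occ"] = init_occ,
                      _["final_occ"] = final_occ);
}
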