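// Numeric kernels: partial-correlation CI tests with a PC-stable skeleton
// search over a correlation matrix, and a small Newton solver for
// multinomial logistic log-likelihoods (used by mixed-type likelihood-ratio
// CI tests).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double fisher_z_p(double r, int n, int k) {
  if (n - k - 3 <= 0) return 1.0;
  if (r > 0.9999999999) r = 0.9999999999;
  if (r < -0.9999999999) r = -0.9999999999;
  double z = 0.5 * std::log((1.0 + r) / (1.0 - r));
  double stat = std::sqrt((double)(n - k - 3)) * std::fabs(z);
  return 2.0 * R::pnorm(stat, 0.0, 1.0, 0, 0);
}

static double pcor_sub(const arma::mat& C, int x, int y,
                       const std::vector<int>& S) {
  int k = (int)S.size();
  if (k == 0) return C(x, y);
  arma::uvec idx(k + 2);
  idx[0] = x; idx[1] = y;
  for (int i = 0; i < k; ++i) idx[i + 2] = S[i];
  arma::mat sub = C.submat(idx, idx);
  arma::mat P;
  if (!arma::inv_sympd(P, sub)) {
    if (!arma::pinv(P, sub)) return 0.0;
  }
  double d = P(0, 0) * P(1, 1);
  if (d <= 0) return 0.0;
  return -P(0, 1) / std::sqrt(d);
}

// [[Rcpp::export]]
double ciGaussCpp(const arma::mat& C, int n, int x, int y,
                  const IntegerVector& S) {
  std::vector<int> Sv(S.size());             // 1-based from R
  for (int i = 0; i < S.size(); ++i) Sv[i] = S[i] - 1;
  double r = pcor_sub(C, x - 1, y - 1, Sv);
  return fisher_z_p(r, n, (int)Sv.size());
}

// next k-combination of {0..m-1} in lexicographic order; returns false when
// exhausted
static bool next_comb(std::vector<int>& c, int m) {
  int k = (int)c.size();
  for (int i = k - 1; i >= 0; --i) {
    if (c[i] < m - (k - i)) {
      ++c[i];
      for (int j = i + 1; j < k; ++j) c[j] = c[j - 1] + 1;
      return true;
    }
  }
  return false;
}

// PC-stable skeleton over a correlation matrix (Fisher-z tests).
// init: logical matrix restricting the starting adjacencies.
// Returns adjacency after edge removal at depths 0..maxDepth.
// [[Rcpp::export]]
LogicalMatrix skeletonGaussCpp(const arma::mat& C, int n, double alpha,
                               int maxDepth, const LogicalMatrix& init,
                               int maxTestsPerSide = 1000) {
  int p = C.n_rows;
  std::vector<std::vector<bool> > adj(p, std::vector<bool>(p, false));
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j && init(i, j)) adj[i][j] = true;

  for (int depth = 0; depth <= maxDepth; ++depth) {
    // stable copy of neighborhoods at the start of this depth
    std::vector<std::vector<int> > nbrs(p);
    bool any = false;
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) if (adj[i][j]) nbrs[i].push_back(j);
      if ((int)nbrs[i].size() > depth) any = true;
    }
    if (!any) break;
    std::vector<std::pair<int,int> > remove;
    for (int x = 0; x < p; ++x) {
      for (int y = x + 1; y < p; ++y) {
        if (!adj[x][y]) continue;
        bool gone = false;
        for (int side = 0; side < 2 && !gone; ++side) {
          int a = side == 0 ? x : y;
          int b = side == 0 ? y : x;
          std::vector<int> cand;
          for (size_t t = 0; t < nbrs[a].size(); ++t)
            if (nbrs[a][t] != b) cand.push_back(nbrs[a][t]);
          int m = (int)cand.size();
          if (m < depth) continue;
          if (depth == 0) {
            if (side == 1) continue;  // empty set tested once
            std::vector<int> S;
            double r = pcor_sub(C, x, y, S);
            if (fisher_z_p(r, n, 0) > alpha) gone = true;
            continue;
          }
          std::vector<int> comb(depth);
          for (int i = 0; i < depth; ++i) comb[i] = i;
          int tested = 0;
          do {
            if (++tested > maxTestsPerSide) break;  // bounded-compute cap
            std::vector<int> S(depth);
            for (int i = 0; i < depth; ++i) S[i] = cand[comb[i]];
            double r = pcor_sub(C, x, y, S);
            if (fisher_z_p(r, n, depth) > alpha) { gone = true; break; }
          } while (next_comb(comb, m));
        }
        if (gone) remove.push_back(std::make_pair(x, y));
      }
    }
    for (size_t t = 0; t < remove.size(); ++t) {
      adj[remove[t].first][remove[t].second] = false;
      adj[remove[t].second][remove[t].first] = false;
    }
  }
  LogicalMatrix out(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) out(i, j) = adj[i][j];
  return out;
}

// Max-p separating-set search for one pair over subsets (up to maxDepth) of
// the candidate lists candX, candY (0-based). Returns the subset with the
// highest p-value and that p-value.
// [[Rcpp::export]]
List maxPSepsetGaussCpp(const arma::mat& C, int n, int x, int y,
                        const IntegerVector& candX,
                        const IntegerVector& candY, int maxDepth,
                        int maxTestsPerSide = 1000) {
  int x0 = x - 1, y0 = y - 1;
  double bestP = -1.0;
  std::vector<int> bestS;
  for (int side = 0; side < 2; ++side) {
    const IntegerVector& cv = side == 0 ? candX : candY;
    std::vector<int> cand;
    for (int i = 0; i < cv.size(); ++i) cand.push_back(cv[i] - 1);
    int m = (int)cand.size();
    int dmax = std::min(maxDepth, m);
    for (int depth = 0; depth <= dmax; ++depth) {
      if (depth == 0) {
        if (side == 1) continue;
        std::vector<int> S;
        double pv = fisher_z_p(pcor_sub(C, x0, y0, S), n, 0);
        if (pv > bestP) { bestP = pv; bestS = S; }
        continue;
      }
      std::vector<int> comb(depth);
      for (int i = 0; i < depth; ++i) comb[i] = i;
      int tested = 0;
      do {
        if (++tested > maxTestsPerSide) break;  // bounded-compute cap
        std::vector<int> S(depth);
        for (int i = 0; i < depth; ++i) S[i] = cand[comb[i]];
        double pv = fisher_z_p(pcor_sub(C, x0, y0, S), n, depth);
        if (pv > bestP) { bestP = pv; bestS = S; }
      } while (next_comb(comb, m));
    }
  }
  IntegerVector S(bestS.size());
  for (size_t i = 0; i < bestS.size(); ++i) S[i] = bestS[i] + 1;
  return List::create(Named("sepset") = S, Named("p") = bestP);
}

// Multinomial logistic log-likelihood, maximized by damped Newton.
// X: n x d design (including intercept); y: 0-based class labels in 0..K-1.
// [[Rcpp::export]]
double mnLoglikCpp(const arma::mat& X, const arma::ivec& y, int K,
                   int maxit = 60, double tol = 1e-9) {
  int n = X.n_rows, d = X.n_cols, m = K - 1;
  if (m <= 0) return 0.0;
  arma::mat Yh(n, m, arma::fill::zeros);
  for (int i = 0; i < n; ++i) if (y[i] > 0) Yh(i, y[i] - 1) = 1.0;
  arma::mat B(d, m, arma::fill::zeros);
  double ridge = 1e-8;

  arma::mat Eta(n, m), P(n, m);
  arma::vec denom(n);
  double ll = -1e300;
  for (int iter = 0; iter < maxit; ++iter) {
    Eta = X * B;
    arma::vec rowmax = arma::max(Eta, 1);
    rowmax.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::mat expEta = arma::exp(Eta.each_col() - rowmax);
    denom = arma::exp(-rowmax) + arma::sum(expEta, 1);
    P = expEta.each_col() / denom;
    double llNew = arma::accu(Yh % Eta) -
      arma::accu(arma::log(denom) + rowmax) -
      0.5 * ridge * arma::accu(B % B);
    if (iter > 0 && std::fabs(llNew - ll) <= tol * (std::fabs(ll) + 1.0)) {
      ll = llNew; break;
    }
    ll = llNew;
    arma::mat G = X.t() * (Yh - P) - ridge * B;      // d x m
    arma::mat H(d * m, d * m, arma::fill::zeros);
    for (int a = 0; a < m; ++a) {
      for (int b = a; b < m; ++b) {
        arma::vec w = a == b ? arma::vec(P.col(a) % (1.0 - P.col(b)))
                             : arma::vec(-P.col(a) % P.col(b));
        arma::mat blk = X.t() * (X.each_col() % w);
        H.submat(a * d, b * d, (a + 1) * d - 1, (b + 1) * d - 1) = blk;
        if (a != b)
          H.submat(b * d, a * d, (b + 1) * d - 1, (a + 1) * d - 1) = blk.t();
      }
    }
    H.diag() += ridge;
    arma::vec step;
    if (!arma::solve(step, H, arma::vectorise(G),
                     arma::solve_opts::likely_sympd)) break;
    // step-halving safeguard
    arma::mat Bnew = B + arma::reshape(step, d, m);
    for (int h = 0; h < 12; ++h) {
      arma::mat EtaN = X * Bnew;
      arma::vec rm = arma::max(EtaN, 1);
      rm.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat eE = arma::exp(EtaN.each_col() - rm);
      arma::vec den = arma::exp(-rm) + arma::sum(eE, 1);
      double llTry = arma::accu(Yh % EtaN) -
        arma::accu(arma::log(den) + rm) -
        0.5 * ridge * arma::accu(Bnew % Bnew);
      if (llTry >= ll - 1e-12) break;
      Bnew = B + (Bnew - B) * 0.5;
    }
    B = Bnew;
  }
  return ll;
}
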