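// Single-site Metropolis sampler over cluster-assignment vectors, with the
// column-model marginals evaluated from sufficient statistics. The chain
// targets P(D|A,K)^beta restricted to assignments with no empty cluster
// (uniform assignment prior on that set), which covers the posterior
// (beta = 1), tempered chains for thermodynamic integration, and the
// P-tilde chain of the tempered harmonic-mean estimator.
//
// Randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes every chain reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct MixState {
  int N, K, Lc, Ln;
  const int *cat;          // N x Lc, 1-based category codes
  const double *num;       // N x Ln
  std::vector<int> cat_k;
  std::vector<std::vector<double>> alpha;  // per categorical column
  std::vector<double> alpha_sum;
  std::vector<double> lg_alpha_sum;        // sum of lgamma(alpha_c)
  std::vector<double> mu0, beta0, a0, b0;  // per numeric column

  std::vector<int> ncl;                    // cluster sizes
  std::vector<std::vector<int>> cnt;       // per cat col: K*k counts
  std::vector<double> s1, s2;              // K x Ln sums (j*Ln + l)

  void init(const IntegerMatrix &catm, const IntegerVector &catk,
            const List &alph, const NumericMatrix &numm,
            const NumericMatrix &hyper, const IntegerVector &labels,
            int K_) {
    N = catm.nrow() > 0 ? catm.nrow() : numm.nrow();
    K = K_;
    Lc = catm.ncol();
    Ln = numm.ncol();
    cat = Lc ? &catm[0] : nullptr;
    num = Ln ? &numm[0] : nullptr;
    cat_k.assign(catk.begin(), catk.end());
    alpha.resize(Lc); alpha_sum.resize(Lc); lg_alpha_sum.resize(Lc);
    for (int l = 0; l < Lc; ++l) {
      NumericVector a = alph[l];
      alpha[l].assign(a.begin(), a.end());
      double s = 0, lg = 0;
      for (double v : alpha[l]) { s += v; lg += R::lgammafn(v); }
      alpha_sum[l] = s; lg_alpha_sum[l] = lg;
    }
    mu0.resize(Ln); beta0.resize(Ln); a0.resize(Ln); b0.resize(Ln);
    for (int l = 0; l < Ln; ++l) {
      mu0[l] = hyper(0, l); beta0[l] = hyper(1, l);
      a0[l] = hyper(2, l); b0[l] = hyper(3, l);
    }
    ncl.assign(K, 0);
    cnt.assign(Lc, std::vector<int>());
    for (int l = 0; l < Lc; ++l) cnt[l].assign((size_t)K * cat_k[l], 0);
    s1.assign((size_t)K * Ln, 0.0);
    s2.assign((size_t)K * Ln, 0.0);
    for (int i = 0; i < N; ++i) add_row(i, labels[i] - 1);
  }

  inline int cat_val(int i, int l) const { return cat[i + (size_t)N * l]; }
  inline double num_val(int i, int l) const { return num[i + (size_t)N * l]; }

  void add_row(int i, int j) {
    ncl[j] += 1;
    for (int l = 0; l < Lc; ++l)
      cnt[l][(size_t)j * cat_k[l] + (cat_val(i, l) - 1)] += 1;
    for (int l = 0; l < Ln; ++l) {
      double x = num_val(i, l);
      s1[(size_t)j * Ln + l] += x;
      s2[(size_t)j * Ln + l] += x * x;
    }
  }

  void remove_row(int i, int j) {
    ncl[j] -= 1;
    for (int l = 0; l < Lc; ++l)
      cnt[l][(size_t)j * cat_k[l] + (cat_val(i, l) - 1)] -= 1;
    for (int l = 0; l < Ln; ++l) {
      double x = num_val(i, l);
      s1[(size_t)j * Ln + l] -= x;
      s2[(size_t)j * Ln + l] -= x * x;
      if (s2[(size_t)j * Ln + l] < 0) s2[(size_t)j * Ln + l] = 0;
    }
  }

  // Log posterior predictive of row i under cluster j (row i must not be
  // counted in j).
  double row_pred(int i, int j) const {
    double lp = 0;
    int n = ncl[j];
    for (int l = 0; l < Lc; ++l) {
      int c = cat_val(i, l) - 1;
      lp += std::log(cnt[l][(size_t)j * cat_k[l] + c] + alpha[l][c]) -
            std::log(n + alpha_sum[l]);
    }
    for (int l = 0; l < Ln; ++l) {
      double x = num_val(i, l);
      double m = n > 0 ? s1[(size_t)j * Ln + l] / n : 0.0;
      double S = s2[(size_t)j * Ln + l] - n * m * m;
      if (S < 0) S = 0;
      double bn = beta0[l] + n;
      double an = a0[l] + 0.5 * n;
      double dev = m - mu0[l];
      double b = b0[l] + 0.5 * S + beta0[l] * n * dev * dev / (2.0 * bn);
      double lam = an * bn / (b * (bn + 1.0));
      double d = x - (beta0[l] * mu0[l] + n * m) / bn;
      lp += -0.5 * std::log(M_PI) + R::lgammafn(an + 0.5) - R::lgammafn(an) +
            0.5 * (std::log(lam) - std::log(2.0 * an)) -
            (an + 0.5) * std::log1p(lam * d * d / (2.0 * an));
    }
    return lp;
  }

  // Full collapsed joint log-likelihood from the sufficient statistics.
  double full_ll() const {
    double ll = 0;
    for (int j = 0; j < K; ++j) {
      int n = ncl[j];
      for (int l = 0; l < Lc; ++l) {
        double s = 0;
        for (int c = 0; c < cat_k[l]; ++c)
          s += R::lgammafn(cnt[l][(size_t)j * cat_k[l] + c] + alpha[l][c]);
        ll += s - lg_alpha_sum[l] + R::lgammafn(alpha_sum[l]) -
              R::lgammafn(n + alpha_sum[l]);
      }
      if (n == 0) continue;
      for (int l = 0; l < Ln; ++l) {
        double m = s1[(size_t)j * Ln + l] / n;
        double S = s2[(size_t)j * Ln + l] - n * m * m;
        if (S < 0) S = 0;
        double bn = beta0[l] + n;
        double an = a0[l] + 0.5 * n;
        double dev = m - mu0[l];
        double b = b0[l] + 0.5 * S + beta0[l] * n * dev * dev / (2.0 * bn);
        ll += R::lgammafn(an) - R::lgammafn(a0[l]) + a0[l] * std::log(b0[l]) -
              an * std::log(b) + 0.5 * (std::log(beta0[l]) - std::log(bn)) -
              0.5 * n * std::log(2.0 * M_PI);
      }
    }
    return ll;
  }
};

inline int rand_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

} // namespace

// [[Rcpp::export]]
List cpp_chain(IntegerMatrix cat, IntegerVector cat_k, List cat_alpha,
               NumericMatrix num, NumericMatrix num_hyper,
               IntegerVector labels, int K, double beta,
               int burnin, int thin, int M) {
  MixState st;
  st.init(cat, cat_k, cat_alpha, num, num_hyper, labels, K);
  std::vector<int> lab(labels.begin(), labels.end());
  for (auto &v : lab) v -= 1;
  int N = st.N;
  NumericVector ll_samples(M);
  long accepted = 0, proposed = 0;
  if (thin < 1) thin = 1;

  auto step = [&]() {
    ++proposed;
    if (K < 2) return;
    int i = rand_int(N);
    int cur = lab[i];
    if (st.ncl[cur] == 1) return;  // move would empty a cluster: reject
    int prop = rand_int(K - 1);
    if (prop >= cur) ++prop;
    st.remove_row(i, cur);
    double delta = st.row_pred(i, prop) - st.row_pred(i, cur);
    if (std::log(unif_rand()) < beta * delta) {
      lab[i] = prop;
      st.add_row(i, prop);
      ++accepted;
    } else {
      st.add_row(i, cur);
    }
  };

  for (int t = 0; t < burnin; ++t) step();
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < thin; ++t) step();
    ll_samples[m] = st.full_ll();
  }

  IntegerVector out_lab(N);
  for (int i = 0; i < N; ++i) out_lab[i] = lab[i] + 1;
  return List::create(_["ll"] = ll_samples, _["labels"] = out_lab,
                      _["accept_rate"] =
                          proposed ? (double)accepted / proposed : 0.0);
}

// [[Rcpp::export]]
double cpp_joint_ll(IntegerMatrix cat, IntegerVector cat_k, List cat_alpha,
                    NumericMatrix num, NumericMatrix num_hyper,
                    IntegerVector labels, int K) {
  MixState st;
  st.init(cat, cat_k, cat_alpha, num, num_hyper, labels, K);
  return st.full_ll();
}

// [[Rcpp::export]]
NumericVector cpp_joint_ll_multi(IntegerMatrix cat, IntegerVector cat_k,
                                 List cat_alpha, NumericMatrix num,
                                 NumericMatrix num_hyper,
                                 IntegerMatrix labels_mat, int K) {
  int M = labels_mat.ncol();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    IntegerVector lab = labels_mat(_, m);
    MixState st;
    st.init(cat, cat_k, cat_alpha, num, num_hyper, lab, K);
    out[m] = st.full_ll();
  }
  return out;
}
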