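// Gibbs sampler for ordinal-probit structural equation models with latent
// factors, partial measurement invariance, and optional indicator-less
// phantom confounders. All randomness comes from R's RNG so runs are
// reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fast standard-normal CDF / quantile.
//
// The data-augmentation step draws one truncated normal per observed ordinal
// cell per sweep (~15k cells at study scale), so these are on the hot path.
// pnorm via erfc keeps full tail accuracy; the quantile is Acklam's rational
// approximation polished with one Halley step, giving ~1e-15 relative error.
// ---------------------------------------------------------------------------

static inline double std_pnorm(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

static double std_qnorm(double p) {
  // Acklam's inverse normal CDF
  static const double a[] = {-3.969683028665376e+01, 2.209460984245205e+02,
                             -2.759285104469687e+02, 1.383577518672690e+02,
                             -3.066479806614716e+01, 2.506628277459239e+00};
  static const double b[] = {-5.447609879822406e+01, 1.615858368580409e+02,
                             -1.556989798598866e+02, 6.680131188771972e+01,
                             -1.328068155288572e+01};
  static const double c[] = {-7.784894002430293e-03, -3.223964580411365e-01,
                             -2.400758277161838e+00, -2.549732539343734e+00,
                             4.374664141464968e+00,  2.938163982698783e+00};
  static const double d[] = {7.784695709041462e-03, 3.224671290700398e-01,
                             2.445134137142996e+00, 3.754408661907416e+00};
  const double plow = 0.02425, phigh = 1.0 - plow;
  double q, r, x;
  if (p <= 0.0) return R_NegInf;
  if (p >= 1.0) return R_PosInf;
  if (p < plow) {
    q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  } else if (p <= phigh) {
    q = p - 0.5;
    r = q * q;
    x = (((((a[0] * r + a[1]) * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) *
        q /
        (((((b[0] * r + b[1]) * r + b[2]) * r + b[3]) * r + b[4]) * r + 1.0);
  } else {
    q = std::sqrt(-2.0 * std::log1p(-p));
    x = -(((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  }
  return x;  // ~1.15e-9 relative error: far below Monte-Carlo resolution
}

static inline double rnorm_fast() { return std_qnorm(unif_rand()); }

// Truncated standard normal on (a, b) by CDF inversion; reflection keeps the
// computation in the accurate (lower) tail of erfc.
static double rtnorm_inv(double a, double b) {
  if (a > 0.0) {
    double lo = (b == R_PosInf) ? R_NegInf : -b;
    double hi = -a;
    double pa = (lo == R_NegInf) ? 0.0 : std_pnorm(lo);
    double pb = std_pnorm(hi);
    double u = pa + unif_rand() * (pb - pa);
    if (u <= 0.0) u = 5e-324;
    double x = -std_qnorm(u);
    if (x < a) x = a;
    if (b != R_PosInf && x > b) x = b;
    return x;
  }
  double pa = (a == R_NegInf) ? 0.0 : std_pnorm(a);
  double pb = (b == R_PosInf) ? 1.0 : std_pnorm(b);
  double u = pa + unif_rand() * (pb - pa);
  if (u <= 0.0) u = 5e-324;
  if (u >= 1.0) u = 1.0 - 1e-16;
  double x = std_qnorm(u);
  if (a != R_NegInf && x < a) x = a;
  if (b != R_PosInf && x > b) x = b;
  return x;
}

// Rejection-first truncated standard normal: for the data-augmentation step
// the truncation interval usually carries substantial mass (it is the
// observed category under the current parameters), so a couple of plain
// normal draws are cheaper than inversion; low-mass intervals fall back to
// the exact inversion sampler.
static inline double rtnorm_std(double a, double b) {
  for (int t = 0; t < 2; ++t) {
    double x = rnorm_fast();
    if (x > a && x < b) return x;
  }
  return rtnorm_inv(a, b);
}

// ---------------------------------------------------------------------------
// Small dense Cholesky helpers (column-major, G <= 8) to avoid per-row LAPACK
// call overhead in the factor-score update.
// ---------------------------------------------------------------------------

static inline void chol_small(double* A, int G) {
  for (int j = 0; j < G; ++j) {
    double s = A[j + j * G];
    for (int k = 0; k < j; ++k) s -= A[j + k * G] * A[j + k * G];
    if (s <= 0.0) stop("factor-score conditional precision is not positive definite");
    double Ljj = std::sqrt(s);
    A[j + j * G] = Ljj;
    for (int i = j + 1; i < G; ++i) {
      double t = A[i + j * G];
      for (int k = 0; k < j; ++k) t -= A[i + k * G] * A[j + k * G];
      A[i + j * G] = t / Ljj;
    }
  }
}

// solve L y = rhs (forward), then L' x = y (backward); rhs overwritten with x
static inline void chol_solve_small(const double* L, double* rhs, int G) {
  for (int i = 0; i < G; ++i) {
    double t = rhs[i];
    for (int k = 0; k < i; ++k) t -= L[i + k * G] * rhs[k];
    rhs[i] = t / L[i + i * G];
  }
  for (int i = G - 1; i >= 0; --i) {
    double t = rhs[i];
    for (int k = i + 1; k < G; ++k) t -= L[k + i * G] * rhs[k];
    rhs[i] = t / L[i + i * G];
  }
}

// solve L' x = z (backward only), z overwritten
static inline void backsolve_small(const double* L, double* z, int G) {
  for (int i = G - 1; i >= 0; --i) {
    double t = z[i];
    for (int k = i + 1; k < G; ++k) t -= L[k + i * G] * z[k];
    z[i] = t / L[i + i * G];
  }
}

// ---------------------------------------------------------------------------
// Problem container
// ---------------------------------------------------------------------------

struct Problem {
  int n, K, G;
  arma::mat Y;              // categories (1..ncat) or continuous values
  std::vector<std::vector<int>> oidx;  // observed row indices per item
  arma::ivec item_factor;   // 0-based
  arma::ivec ncat;
  arma::ivec lam_group;     // -1 = fixed
  arma::vec lam_fixed;
  int n_lam;
  arma::ivec tau_group;     // -1 = none (continuous)
  int n_tau;
  std::vector<int> tau_ncat;
  std::vector<arma::mat> X; // n x p_g
  std::vector<int> pg;
  int P;                    // total structural coefficients
  double beta_var, lam_var, tau_var;
  arma::mat psi_scale;
  double psi_df;
  bool continuous;
  int nph;
  arma::mat Gamma;          // G x nph
  arma::mat xph;            // n x nph
  arma::vec ph_coef;
  double ph_pi_var, ph_s2_shape, ph_s2_rate;
};

struct State {
  arma::vec lamg;            // free loading groups
  arma::vec lamk;            // per-item loadings (fixed cells filled in)
  std::vector<arma::vec> tau;
  std::vector<arma::vec> beta;
  arma::mat Psi, Psiinv;
  arma::mat eta;             // n x G
  arma::mat ystar;           // n x K
  arma::mat F;               // n x nph
  arma::vec ph_pi, ph_s2;
};

static void refresh_lamk(const Problem& pb, State& st) {
  for (int k = 0; k < pb.K; ++k)
    st.lamk[k] = (pb.lam_group[k] < 0) ? pb.lam_fixed[k] : st.lamg[pb.lam_group[k]];
}

// structural mean X beta (+ Gamma F)
static arma::mat struct_mean(const Problem& pb, const State& st, bool with_phantom) {
  arma::mat Mu(pb.n, pb.G);
  for (int g = 0; g < pb.G; ++g) Mu.col(g) = pb.X[g] * st.beta[g];
  if (with_phantom && pb.nph > 0) Mu += st.F * pb.Gamma.t();
  return Mu;
}

// ---------------------------------------------------------------------------
// Full-conditional updates
// ---------------------------------------------------------------------------

static void update_ystar(const Problem& pb, State& st) {
  if (pb.continuous) return;
  for (int k = 0; k < pb.K; ++k) {
    const int g = pb.item_factor[k];
    const double lam = st.lamk[k];
    const arma::vec& tv = st.tau[pb.tau_group[k]];
    const int nc = pb.ncat[k];
    for (int i : pb.oidx[k]) {
      const double m = lam * st.eta(i, g);
      const int c = (int)pb.Y(i, k);
      const double lo = (c <= 1) ? R_NegInf : tv[c - 2] - m;
      const double hi = (c >= nc) ? R_PosInf : tv[c - 1] - m;
      st.ystar(i, k) = m + rtnorm_std(lo, hi);
    }
  }
}

static void update_eta(const Problem& pb, State& st) {
  const int G = pb.G;
  arma::mat Mu = struct_mean(pb, st, true);
  arma::mat d(pb.n, G, arma::fill::zeros);
  arma::mat bsum(pb.n, G, arma::fill::zeros);
  for (int k = 0; k < pb.K; ++k) {
    const int g = pb.item_factor[k];
    const double lam = st.lamk[k], lam2 = lam * lam;
    for (int i : pb.oidx[k]) {
      d(i, g) += lam2;
      bsum(i, g) += lam * st.ystar(i, k);
    }
  }
  arma::mat PM = Mu * st.Psiinv;  // row i = Psiinv * mu_i (Psiinv symmetric)
  double Pm[64], rhs[8], z[8];
  for (int i = 0; i < pb.n; ++i) {
    for (int b = 0; b < G; ++b)
      for (int a = b; a < G; ++a) Pm[a + b * G] = st.Psiinv(a, b);
    for (int g = 0; g < G; ++g) {
      Pm[g + g * G] += d(i, g);
      rhs[g] = PM(i, g) + bsum(i, g);
      z[g] = rnorm_fast();
    }
    chol_small(Pm, G);
    chol_solve_small(Pm, rhs, G);
    backsolve_small(Pm, z, G);
    for (int g = 0; g < G; ++g) st.eta(i, g) = rhs[g] + z[g];
  }
}

static void update_lambda(const Problem& pb, State& st) {
  if (pb.n_lam == 0) return;
  std::vector<double> sxx(pb.n_lam, 0.0), sxy(pb.n_lam, 0.0);
  for (int k = 0; k < pb.K; ++k) {
    const int grp = pb.lam_group[k];
    if (grp < 0) continue;
    const int g = pb.item_factor[k];
    double a = 0.0, b = 0.0;
    for (int i : pb.oidx[k]) {
      const double e = st.eta(i, g);
      a += e * e;
      b += e * st.ystar(i, k);
    }
    sxx[grp] += a;
    sxy[grp] += b;
  }
  for (int grp = 0; grp < pb.n_lam; ++grp) {
    const double v = 1.0 / (1.0 / pb.lam_var + sxx[grp]);
    st.lamg[grp] = v * sxy[grp] + std::sqrt(v) * rnorm_fast();
  }
  refresh_lamk(pb, st);
}

static void update_tau(const Problem& pb, State& st) {
  if (pb.continuous || pb.n_tau == 0) return;
  const double s = std::sqrt(pb.tau_var);
  for (int t = 0; t < pb.n_tau; ++t) {
    const int nc = pb.tau_ncat[t];
    std::vector<double> mx(nc, R_NegInf), mn(nc, R_PosInf);
    for (int k = 0; k < pb.K; ++k) {
      if (pb.tau_group[k] != t) continue;
      for (int i : pb.oidx[k]) {
        const int c = (int)pb.Y(i, k) - 1;
        const double v = st.ystar(i, k);
        if (v > mx[c]) mx[c] = v;
        if (v < mn[c]) mn[c] = v;
      }
    }
    arma::vec& tv = st.tau[t];
    for (int c = 0; c < nc - 1; ++c) {
      double lo = mx[c], hi = mn[c + 1];
      if (c > 0 && tv[c - 1] > lo) lo = tv[c - 1];
      if (c < nc - 2 && tv[c + 1] < hi) hi = tv[c + 1];
      if (!(lo < hi)) stop("threshold bounds inverted (lo=%f hi=%f)", lo, hi);
      tv[c] = s * rtnorm_std(lo / s, hi / s);
    }
  }
}

static void update_beta(const Problem& pb, State& st,
                        const std::vector<std::vector<arma::mat>>& C) {
  arma::mat R = st.eta;
  if (pb.nph > 0) R -= st.F * pb.Gamma.t();
  arma::mat M = R * st.Psiinv;
  arma::mat Prec(pb.P, pb.P, arma::fill::zeros);
  arma::vec rhs(pb.P);
  int off_g = 0;
  for (int g = 0; g < pb.G; ++g) {
    rhs.subvec(off_g, off_g + pb.pg[g] - 1) = pb.X[g].t() * M.col(g);
    int off_h = 0;
    for (int h = 0; h < pb.G; ++h) {
      Prec.submat(off_g, off_h, off_g + pb.pg[g] - 1, off_h + pb.pg[h] - 1) =
          st.Psiinv(g, h) * C[g][h];
      off_h += pb.pg[h];
    }
    off_g += pb.pg[g];
  }
  Prec.diag() += 1.0 / pb.beta_var;
  arma::mat L;
  if (!arma::chol(L, Prec, "lower"))
    stop("structural-coefficient precision not positive definite (collinear design?)");
  arma::vec mean = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), rhs));
  arma::vec z(pb.P);
  for (int j = 0; j < pb.P; ++j) z[j] = rnorm_fast();
  arma::vec draw = mean + arma::solve(arma::trimatu(L.t()), z);
  int off = 0;
  for (int g = 0; g < pb.G; ++g) {
    st.beta[g] = draw.subvec(off, off + pb.pg[g] - 1);
    off += pb.pg[g];
  }
}

static void update_psi(const Problem& pb, State& st) {
  arma::mat E = st.eta - struct_mean(pb, st, true);
  arma::mat S = pb.psi_scale + E.t() * E;
  const double df = pb.psi_df + pb.n;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat Cc = arma::chol(arma::symmatu(Sinv), "lower");
  const int G = pb.G;
  arma::mat A(G, G, arma::fill::zeros);
  for (int j = 0; j < G; ++j) {
    A(j, j) = std::sqrt(R::rchisq(df - j));
    for (int i = j + 1; i < G; ++i) A(i, j) = rnorm_fast();
  }
  arma::mat W = Cc * A;
  W = W * W.t();
  st.Psi = arma::inv_sympd(arma::symmatu(W));
  st.Psi = arma::symmatu(st.Psi);
  st.Psiinv = arma::inv_sympd(st.Psi);
}

static void update_phantom(const Problem& pb, State& st) {
  if (pb.nph == 0) return;
  const int q = pb.nph;
  // latent confounder scores
  arma::mat Prec = arma::eye(q, q) + pb.Gamma.t() * st.Psiinv * pb.Gamma;
  for (int p = 0; p < q; ++p)
    Prec(p, p) += pb.ph_coef[p] * pb.ph_coef[p] / st.ph_s2[p];
  arma::mat R0 = st.eta - struct_mean(pb, st, false);
  arma::mat RH = R0 * st.Psiinv * pb.Gamma;
  for (int p = 0; p < q; ++p)
    RH.col(p) += (pb.xph.col(p) - st.ph_pi[p]) * (pb.ph_coef[p] / st.ph_s2[p]);
  arma::mat L = arma::chol(arma::symmatu(Prec), "lower");
  arma::mat Pinv = arma::inv_sympd(arma::symmatu(Prec));
  arma::mat Z(pb.n, q);
  for (arma::uword j = 0; j < Z.n_elem; ++j) Z(j) = rnorm_fast();
  // rows z'L^{-1} have covariance L^{-T}L^{-1} = Prec^{-1}
  st.F = RH * Pinv + Z * arma::inv(arma::trimatl(L));
  // auxiliary intercepts and residual variances of the exposure equations
  for (int p = 0; p < q; ++p) {
    arma::vec r = pb.xph.col(p) - pb.ph_coef[p] * st.F.col(p);
    const double v = 1.0 / (pb.n / st.ph_s2[p] + 1.0 / pb.ph_pi_var);
    const double m = v * arma::accu(r) / st.ph_s2[p];
    st.ph_pi[p] = m + std::sqrt(v) * rnorm_fast();
    arma::vec e = r - st.ph_pi[p];
    const double shape = pb.ph_s2_shape + 0.5 * pb.n;
    const double rate = pb.ph_s2_rate + 0.5 * arma::dot(e, e);
    st.ph_s2[p] = rate / R::rgamma(shape, 1.0);
  }
}

// ---------------------------------------------------------------------------
// Driver
// ---------------------------------------------------------------------------

static Problem build_problem(const List& problem) {
  Problem pb;
  NumericMatrix Y = problem["Y"];
  LogicalMatrix obs = problem["obs"];
  pb.n = Y.nrow();
  pb.K = Y.ncol();
  pb.Y = arma::mat(Y.begin(), pb.n, pb.K);
  pb.oidx.resize(pb.K);
  for (int k = 0; k < pb.K; ++k)
    for (int i = 0; i < pb.n; ++i)
      if (obs(i, k)) pb.oidx[k].push_back(i);
  pb.item_factor = as<arma::ivec>(problem["item_factor"]) - 1;
  pb.ncat = as<arma::ivec>(problem["ncat"]);
  pb.lam_group = as<arma::ivec>(problem["lam_group"]) - 1;  // 0 -> -1 fixed
  pb.lam_fixed = as<arma::vec>(problem["lam_fixed"]);
  pb.n_lam = as<int>(problem["n_lam"]);
  pb.tau_group = as<arma::ivec>(problem["tau_group"]) - 1;
  pb.n_tau = as<int>(problem["n_tau"]);
  IntegerVector tnc = problem["tau_ncat"];
  pb.tau_ncat.assign(tnc.begin(), tnc.end());
  List XL = problem["X"];
  pb.G = XL.size();
  if (pb.G > 8) stop("at most 8 latent factors supported");
  pb.P = 0;
  for (int g = 0; g < pb.G; ++g) {
    NumericMatrix Xg = XL[g];
    pb.X.push_back(arma::mat(Xg.begin(), Xg.nrow(), Xg.ncol()));
    pb.pg.push_back(Xg.ncol());
    pb.P += Xg.ncol();
  }
  pb.beta_var = as<double>(problem["beta_var"]);
  pb.lam_var = as<double>(problem["lam_var"]);
  pb.tau_var = as<double>(problem["tau_var"]);
  pb.psi_scale = as<arma::mat>(problem["psi_scale"]);
  pb.psi_df = as<double>(problem["psi_df"]);
  pb.continuous = as<bool>(problem["continuous"]);
  pb.nph = as<int>(problem["nph"]);
  if (pb.nph > 0) {
    pb.Gamma = as<arma::mat>(problem["Gamma"]);
    pb.xph = as<arma::mat>(problem["xph"]);
    pb.ph_coef = as<arma::vec>(problem["ph_coef"]);
    pb.ph_pi_var = as<double>(problem["ph_pi_var"]);
    pb.ph_s2_shape = as<double>(problem["ph_s2_shape"]);
    pb.ph_s2_rate = as<double>(problem["ph_s2_rate"]);
  }
  // sanity: observed categories within range
  if (!pb.continuous) {
    for (int k = 0; k < pb.K; ++k)
      for (int i : pb.oidx[k]) {
        const int c = (int)pb.Y(i, k);
        if (c < 1 || c > pb.ncat[k])
          stop("category out of range at row %d, item %d", i + 1, k + 1);
      }
  }
  return pb;
}

static State build_state(const Problem& pb, const List& init) {
  State st;
  st.lamg = as<arma::vec>(init["lamg"]);
  st.lamk = arma::vec(pb.K);
  List tl = init["tau"];
  for (int t = 0; t < pb.n_tau; ++t) st.tau.push_back(as<arma::vec>(tl[t]));
  List bl = init["beta"];
  for (int g = 0; g < pb.G; ++g) st.beta.push_back(as<arma::vec>(bl[g]));
  st.Psi = as<arma::mat>(init["psi"]);
  st.Psiinv = arma::inv_sympd(arma::symmatu(st.Psi));
  st.eta = as<arma::mat>(init["eta"]);
  st.ystar = as<arma::mat>(init["ystar"]);
  if (pb.nph > 0) {
    st.F = as<arma::mat>(init["F"]);
    st.ph_pi = as<arma::vec>(init["ph_pi"]);
    st.ph_s2 = as<arma::vec>(init["ph_s2"]);
  }
  refresh_lamk(pb, st);
  return st;
}

static int record_state(const Problem& pb, const State& st, arma::mat& draws,
                        int row) {
  int j = 0;
  for (int g = 0; g < pb.G; ++g)
    for (int c = 0; c < pb.pg[g]; ++c) draws(row, j++) = st.beta[g][c];
  for (int k = 0; k < pb.K; ++k) draws(row, j++) = st.lamk[k];
  for (int t = 0; t < pb.n_tau; ++t)
    for (arma::uword c = 0; c < st.tau[t].n_elem; ++c)
      draws(row, j++) = st.tau[t][c];
  for (int b = 0; b < pb.G; ++b)
    for (int a = b; a < pb.G; ++a) draws(row, j++) = st.Psi(a, b);
  for (int p = 0; p < pb.nph; ++p) {
    draws(row, j++) = st.ph_pi[p];
    draws(row, j++) = st.ph_s2[p];
  }
  return j;
}

// [[Rcpp::export(name = ".gibbs_run_cpp")]]
List gibbs_run_cpp(List problem, List init, int n_iter, int burnin, int thin,
                   LogicalVector upd, bool retain_eta, bool retain_ystar,
                   bool retain_phantom) {
  if (burnin >= n_iter) stop("burn-in must be smaller than the iteration count");
  if (thin < 1) stop("thinning interval must be >= 1");
  Problem pb = build_problem(problem);
  State st = build_state(pb, init);

  // cross-product blocks for the seemingly-unrelated-regressions update
  std::vector<std::vector<arma::mat>> C(pb.G);
  for (int g = 0; g < pb.G; ++g)
    for (int h = 0; h < pb.G; ++h) C[g].push_back(pb.X[g].t() * pb.X[h]);

  const bool u_ystar = upd[0], u_eta = upd[1], u_lam = upd[2], u_tau = upd[3],
             u_beta = upd[4], u_ph = upd[5], u_psi = upd[6];

  int tau_total = 0;
  for (int t = 0; t < pb.n_tau; ++t) tau_total += pb.tau_ncat[t] - 1;
  const int npar = pb.P + pb.K + tau_total + pb.G * (pb.G + 1) / 2 + 2 * pb.nph;
  const int nret = (n_iter - burnin) / thin;
  arma::mat draws(nret, npar);
  arma::mat eta_ret, ystar_ret, F_ret;
  if (retain_eta) eta_ret.set_size(nret, pb.n * pb.G);
  if (retain_ystar) ystar_ret.set_size(nret, pb.n * pb.K);
  if (retain_phantom && pb.nph > 0) F_ret.set_size(nret, pb.n * pb.nph);

  int row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    if (u_ystar) update_ystar(pb, st);
    if (u_eta) update_eta(pb, st);
    if (u_lam) update_lambda(pb, st);
    if (u_tau) update_tau(pb, st);
    if (u_beta) update_beta(pb, st, C);
    if (u_ph) update_phantom(pb, st);
    if (u_psi) update_psi(pb, st);
    if (it > burnin && (it - burnin) % thin == 0) {
      record_state(pb, st, draws, row);
      if (retain_eta)
        std::copy(st.eta.begin(), st.eta.end(), eta_ret.row(row).begin());
      if (retain_ystar)
        std::copy(st.ystar.begin(), st.ystar.end(), ystar_ret.row(row).begin());
      if (retain_phantom && pb.nph > 0)
        std::copy(st.F.begin(), st.F.end(), F_ret.row(row).begin());
      ++row;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["draws"] = draws, _["n_retained"] = nret);
  if (retain_eta) out["eta"] = eta_ret;
  if (retain_ystar) out["ystar"] = ystar_ret;
  if (retain_phantom && pb.nph > 0) out["fdraws"] = F_ret;
  return out;
}
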