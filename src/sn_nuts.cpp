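// Skew-normal hierarchical spline regression: log posterior with analytic
// gradient, and a No-U-Turn sampler (slice variant, dual-averaging step size,
// diagonal mass adaptation). R's RNG is used throughout so set.seed() on the
// R side makes chains reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// Inverse Mills ratio phi(x)/Phi(x), stable in both tails.
inline double mills(double x) {
  return std::exp(R::dnorm(x, 0.0, 1.0, 1) - R::pnorm(x, 0.0, 1.0, 1, 1));
}

struct SnModel {
  // data
  std::vector<double> y, age;      // response, standardized age (random slope)
  std::vector<double> X;           // n x p fixed-effect matrix, column-major
  std::vector<int> ind, site;      // 0-based grouping indices
  int n, p, nI, nS, dim;
  // priors
  std::vector<double> pm, ps;      // beta prior mean / sd (length p)
  double tau_re, tau_sigma, tau_alpha;
  // parameter block offsets within theta
  int o_u, o_w, o_s, o_lsu, o_lsw, o_lss, o_lsig, o_alpha;

  SnModel(const NumericVector& y_, const NumericMatrix& X_,
          const IntegerVector& ind_, const IntegerVector& site_,
          const NumericVector& age_, int nI_, int nS_,
          const NumericVector& pm_, const NumericVector& ps_,
          double tau_re_, double tau_sigma_, double tau_alpha_) {
    n = y_.size(); p = X_.ncol(); nI = nI_; nS = nS_;
    y.assign(y_.begin(), y_.end());
    age.assign(age_.begin(), age_.end());
    X.assign(X_.begin(), X_.end());
    ind.assign(ind_.begin(), ind_.end());
    site.assign(site_.begin(), site_.end());
    pm.assign(pm_.begin(), pm_.end());
    ps.assign(ps_.begin(), ps_.end());
    tau_re = tau_re_; tau_sigma = tau_sigma_; tau_alpha = tau_alpha_;
    o_u = p; o_w = p + nI; o_s = p + 2 * nI;
    o_lsu = p + 2 * nI + nS; o_lsw = o_lsu + 1; o_lss = o_lsu + 2;
    o_lsig = o_lsu + 3; o_alpha = o_lsu + 4;
    dim = p + 2 * nI + nS + 5;
  }

  // log posterior and gradient; returns -Inf (grad untouched) on overflow
  double lp_grad(const std::vector<double>& th, std::vector<double>& g) const {
    const double c = std::sqrt(2.0 / M_PI);
    double lsu = th[o_lsu], lsw = th[o_lsw], lss = th[o_lss];
    double lsig = th[o_lsig], alpha = th[o_alpha];
    if (lsig > 40 || lsu > 40 || lsw > 40 || lss > 40) return R_NegInf;
    double sdu = std::exp(lsu), sdw = std::exp(lsw), sds = std::exp(lss);
    double sigma = std::exp(lsig);
    double delta = alpha / std::sqrt(1.0 + alpha * alpha);
    double ddelta = std::pow(1.0 + alpha * alpha, -1.5);

    std::fill(g.begin(), g.end(), 0.0);
    double lp = 0.0;
    double sum_dsig = 0.0, sum_dalpha = 0.0;

    for (int i = 0; i < n; ++i) {
      double mu = 0.0;
      for (int j = 0; j < p; ++j) mu += X[i + (size_t)j * n] * th[j];
      mu += sdu * th[o_u + ind[i]];
      mu += sdw * th[o_w + ind[i]] * age[i];
      mu += sds * th[o_s + site[i]];
      // mean parametrization: xi = mu - sigma*delta*c, omega = sigma
      double z = (y[i] - mu) / sigma + delta * c;
      double az = alpha * z;
      double lcdf = R::pnorm(az, 0.0, 1.0, 1, 1);
      lp += M_LN2 - lsig - 0.5 * M_LN_SQRT_2PI * 2.0 - 0.5 * z * z + lcdf;
      if (!R_finite(lp)) return R_NegInf;
      double zeta = mills(az);
      double gmu = z / sigma - (alpha / sigma) * zeta;          // dloglik/dmu
      double zc = z - delta * c;                                 // (y-mu)/sigma
      sum_dsig += -1.0 / sigma + zc * (z - alpha * zeta) / sigma;
      double dzda = c * ddelta;
      sum_dalpha += -z * dzda + zeta * (z + alpha * dzda);
      // accumulate gradient pieces
      for (int j = 0; j < p; ++j) g[j] += X[i + (size_t)j * n] * gmu;
      g[o_u + ind[i]] += sdu * gmu;
      g[o_w + ind[i]] += sdw * age[i] * gmu;
      g[o_s + site[i]] += sds * gmu;
      g[o_lsu] += sdu * th[o_u + ind[i]] * gmu;
      g[o_lsw] += sdw * th[o_w + ind[i]] * age[i] * gmu;
      g[o_lss] += sds * th[o_s + site[i]] * gmu;
    }

    // priors: beta ~ N(pm, ps)
    for (int j = 0; j < p; ++j) {
      double r = (th[j] - pm[j]) / ps[j];
      lp += -0.5 * r * r;
      g[j] += -r / ps[j];
    }
    // raw random effects ~ N(0,1)
    for (int k = 0; k < nI; ++k) {
      lp += -0.5 * th[o_u + k] * th[o_u + k]; g[o_u + k] += -th[o_u + k];
      lp += -0.5 * th[o_w + k] * th[o_w + k]; g[o_w + k] += -th[o_w + k];
    }
    for (int k = 0; k < nS; ++k) {
      lp += -0.5 * th[o_s + k] * th[o_s + k]; g[o_s + k] += -th[o_s + k];
    }
    // half-normal priors on the sds, with log-scale Jacobian
    lp += -0.5 * sdu * sdu / (tau_re * tau_re) + lsu;
    g[o_lsu] += -sdu * sdu / (tau_re * tau_re) + 1.0;
    lp += -0.5 * sdw * sdw / (tau_re * tau_re) + lsw;
    g[o_lsw] += -sdw * sdw / (tau_re * tau_re) + 1.0;
    lp += -0.5 * sds * sds / (tau_re * tau_re) + lss;
    g[o_lss] += -sds * sds / (tau_re * tau_re) + 1.0;
    lp += -0.5 * sigma * sigma / (tau_sigma * tau_sigma) + lsig;
    g[o_lsig] = sigma * sum_dsig - sigma * sigma / (tau_sigma * tau_sigma) + 1.0;
    lp += -0.5 * alpha * alpha / (tau_alpha * tau_alpha);
    g[o_alpha] = sum_dalpha - alpha / (tau_alpha * tau_alpha);
    if (!R_finite(lp)) return R_NegInf;
    return lp;
  }
};

typedef std::vector<double> vec;

struct Hamiltonian {
  const SnModel& m;
  const vec& minv;   // inverse mass (diagonal)
  Hamiltonian(const SnModel& m_, const vec& minv_) : m(m_), minv(minv_) {}
  double kinetic(const vec& r) const {
    double k = 0.0;
    for (size_t j = 0; j < r.size(); ++j) k += 0.5 * r[j] * r[j] * minv[j];
    return k;
  }
  // one leapfrog step; returns log posterior at the new position
  double leapfrog(vec& th, vec& r, double eps, vec& g) const {
    double lp = m.lp_grad(th, g);
    if (!R_finite(lp)) return R_NegInf;
    for (size_t j = 0; j < r.size(); ++j) r[j] += 0.5 * eps * g[j];
    for (size_t j = 0; j < r.size(); ++j) th[j] += eps * minv[j] * r[j];
    lp = m.lp_grad(th, g);
    if (!R_finite(lp)) return R_NegInf;
    for (size_t j = 0; j < r.size(); ++j) r[j] += 0.5 * eps * g[j];
    return lp;
  }
};

struct Tree {
  vec th_minus, r_minus, th_plus, r_plus, th_prop;
  double n_prime;       // slice-acceptable count
  bool s_prime;         // no stopping criterion met
  double alpha_sum;     // sum of Metropolis acceptance stats
  int n_alpha;
  bool divergent;
};

bool no_uturn(const vec& th_minus, const vec& th_plus,
              const vec& r_minus, const vec& r_plus, const vec& minv) {
  double a = 0.0, b = 0.0;
  for (size_t j = 0; j < th_minus.size(); ++j) {
    double d = th_plus[j] - th_minus[j];
    a += d * minv[j] * r_minus[j];
    b += d * minv[j] * r_plus[j];
  }
  return (a >= 0.0) && (b >= 0.0);
}

void build_tree(const Hamiltonian& H, const vec& th, const vec& r,
                double logu, int v, int depth, double eps, double joint0,
                Tree& out, vec& scratch_g) {
  if (depth == 0) {
    vec th1 = th, r1 = r;
    double lp = H.leapfrog(th1, r1, v * eps, scratch_g);
    double joint = R_finite(lp) ? lp - H.kinetic(r1) : R_NegInf;
    out.th_minus = th1; out.r_minus = r1;
    out.th_plus = th1;  out.r_plus = r1;
    out.th_prop = th1;
    out.n_prime = (logu <= joint) ? 1.0 : 0.0;
    out.divergent = !R_finite(joint) || (logu > joint + 1000.0);
    out.s_prime = !out.divergent;
    double a = joint - joint0;
    out.alpha_sum = (a > 0.0) ? 1.0 : std::exp(a);
    if (!R_finite(out.alpha_sum)) out.alpha_sum = 0.0;
    out.n_alpha = 1;
    return;
  }
  build_tree(H, th, r, logu, v, depth - 1, eps, joint0, out, scratch_g);
  if (!out.s_prime) return;
  Tree t2;
  if (v == -1)
    build_tree(H, out.th_minus, out.r_minus, logu, v, depth - 1, eps, joint0,
               t2, scratch_g);
  else
    build_tree(H, out.th_plus, out.r_plus, logu, v, depth - 1, eps, joint0,
               t2, scratch_g);
  if (v == -1) { out.th_minus = t2.th_minus; out.r_minus = t2.r_minus; }
  else         { out.th_plus = t2.th_plus;   out.r_plus = t2.r_plus; }
  double ntot = out.n_prime + t2.n_prime;
  if (ntot > 0.0 && unif_rand() < t2.n_prime / ntot) out.th_prop = t2.th_prop;
  out.n_prime = ntot;
  out.alpha_sum += t2.alpha_sum;
  out.n_alpha += t2.n_alpha;
  out.divergent = out.divergent || t2.divergent;
  out.s_prime = t2.s_prime && !t2.divergent &&
    no_uturn(out.th_minus, out.th_plus, out.r_minus, out.r_plus, H.minv);
}

double find_initial_eps(const Hamiltonian& H, const vec& th0, vec& scratch_g) {
  double eps = 1.0;
  vec r0(th0.size());
  for (size_t j = 0; j < r0.size(); ++j)
    r0[j] = norm_rand() / std::sqrt(H.minv[j]);
  double lp0 = H.m.lp_grad(const_cast<vec&>(th0), scratch_g);
  double joint0 = lp0 - H.kinetic(r0);
  vec th = th0, r = r0;
  double lp = H.leapfrog(th, r, eps, scratch_g);
  double joint = R_finite(lp) ? lp - H.kinetic(r) : R_NegInf;
  double a = (joint - joint0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= std::pow(2.0, a);
    th = th0; r = r0;
    lp = H.leapfrog(th, r, eps, scratch_g);
    joint = R_finite(lp) ? lp - H.kinetic(r) : R_NegInf;
    double diff = joint - joint0;
    if (a == 1.0 && diff <= std::log(0.5)) break;
    if (a == -1.0 && diff >= std::log(0.5)) break;
    if (eps < 1e-10 || eps > 1e7) break;
  }
  return std::max(1e-8, std::min(eps, 10.0));
}

} // namespace

// [[Rcpp::export(name = ".sn_lp_grad")]]
List sn_lp_grad(NumericVector theta, NumericVector y, NumericMatrix X,
                IntegerVector ind, IntegerVector site, NumericVector age,
                int n_ind, int n_site, NumericVector prior_mean,
                NumericVector prior_sd, double tau_re, double tau_sigma,
                double tau_alpha) {
  SnModel m(y, X, ind, site, age, n_ind, n_site, prior_mean, prior_sd,
            tau_re, tau_sigma, tau_alpha);
  if ((int)theta.size() != m.dim) stop("theta has wrong length");
  vec th(theta.begin(), theta.end()), g(m.dim);
  double lp = m.lp_grad(th, g);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// [[Rcpp::export(name = ".sn_nuts_chain")]]
List sn_nuts_chain(NumericVector init, NumericVector y, NumericMatrix X,
                   IntegerVector ind, IntegerVector site, NumericVector age,
                   int n_ind, int n_site, NumericVector prior_mean,
                   NumericVector prior_sd, double tau_re, double tau_sigma,
                   double tau_alpha, int n_iter, int n_warmup,
                   double adapt_delta, int max_treedepth) {
  SnModel m(y, X, ind, site, age, n_ind, n_site, prior_mean, prior_sd,
            tau_re, tau_sigma, tau_alpha);
  if ((int)init.size() != m.dim) stop("init has wrong length");
  RNGScope scope;
  int dim = m.dim;
  vec minv(dim, 1.0);
  vec th(init.begin(), init.end()), g(dim);
  if (!R_finite(m.lp_grad(th, g)))
    stop("non-finite log posterior at the initial values");

  Hamiltonian H(m, minv);
  double eps = find_initial_eps(H, th, g);
  // dual averaging state
  double mu_da = std::log(10.0 * eps), log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(std::max(n_keep, 0), dim);
  IntegerVector treedepths(std::max(n_keep, 0));
  int n_divergent = 0;
  double accept_sum = 0.0;

  // windowed variance accumulation for the diagonal metric
  int var_lo = n_warmup / 4, var_hi = (3 * n_warmup) / 4;
  vec mean_acc(dim, 0.0), m2_acc(dim, 0.0);
  int var_n = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    vec r0(dim);
    for (int j = 0; j < dim; ++j) r0[j] = norm_rand() / std::sqrt(minv[j]);
    double lp = m.lp_grad(th, g);
    double joint0 = lp - H.kinetic(r0);
    double logu = joint0 - R::exp_rand();

    vec th_minus = th, th_plus = th, r_minus = r0, r_plus = r0, th_new = th;
    double n_acc = 1.0;
    bool s = true;
    double alpha_sum = 0.0;
    int n_alpha = 0, depth = 0;
    while (s && depth < max_treedepth) {
      int v = (unif_rand() < 0.5) ? -1 : 1;
      Tree t;
      if (v == -1) build_tree(H, th_minus, r_minus, logu, v, depth, eps, joint0, t, g);
      else         build_tree(H, th_plus,  r_plus,  logu, v, depth, eps, joint0, t, g);
      if (v == -1) { th_minus = t.th_minus; r_minus = t.r_minus; }
      else         { th_plus = t.th_plus;   r_plus = t.r_plus; }
      if (t.divergent && it >= n_warmup) ++n_divergent;
      if (t.s_prime && unif_rand() < t.n_prime / n_acc) th_new = t.th_prop;
      n_acc += t.n_prime;
      alpha_sum += t.alpha_sum;
      n_alpha += t.n_alpha;
      s = t.s_prime &&
        no_uturn(th_minus, th_plus, r_minus, r_plus, minv);
      ++depth;
    }
    th = th_new;
    double a_stat = (n_alpha > 0) ? alpha_sum / n_alpha : 0.0;

    if (it < n_warmup) {
      // dual averaging
      ++da_count;
      double frac = 1.0 / (da_count + t0);
      h_bar = (1.0 - frac) * h_bar + frac * (adapt_delta - a_stat);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma * h_bar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      eps = std::max(1e-10, std::min(eps, 1e3));
      // metric window
      if (it >= var_lo && it < var_hi) {
        ++var_n;
        for (int j = 0; j < dim; ++j) {
          double d = th[j] - mean_acc[j];
          mean_acc[j] += d / var_n;
          m2_acc[j] += d * (th[j] - mean_acc[j]);
        }
      }
      if (it == var_hi - 1 && var_n > 10) {
        for (int j = 0; j < dim; ++j) {
          double v_j = m2_acc[j] / (var_n - 1);
          double reg = (var_n / (var_n + 5.0)) * v_j + 1e-3 * (5.0 / (var_n + 5.0));
          minv[j] = std::max(reg, 1e-8);
        }
        // restart step-size adaptation around the current step size
        eps = find_initial_eps(H, th, g);
        mu_da = std::log(10.0 * eps);
        h_bar = 0.0; log_eps_bar = std::log(eps); da_count = 0;
      }
      if (it == n_warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      int k = it - n_warmup;
      for (int j = 0; j < dim; ++j) draws(k, j) = th[j];
      treedepths[k] = depth;
      accept_sum += a_stat;
    }
  }
  return List::create(
    _["draws"] = draws,
    _["step_size"] = eps,
    _["divergences"] = n_divergent,
    _["treedepth"] = treedepths,
    _["mean_accept"] = (n_keep > 0) ? accept_sum / n_keep : NA_REAL,
    _["inv_mass"] = NumericVector(minv.begin(), minv.end()));
}

// Exact two-sided permutation p-value for the Spearman statistic: enumerates
// all n! pairings of the (untied) rank vectors. Feasible for n <= 9.
// [[Rcpp::export(name = ".spearman_exact_perm")]]
double spearman_exact_perm(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n != (int)ry.size()) stop("length mismatch");
  if (n > 10) stop("exact permutation limited to n <= 10");
  std::vector<double> x(rx.begin(), rx.end()), yv(ry.begin(), ry.end());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += yv[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += (x[i] - mx) * (x[i] - mx);
    sy += (yv[i] - my) * (yv[i] - my);
    sxy += (x[i] - mx) * (yv[i] - my);
  }
  if (sx <= 0 || sy <= 0) stop("constant rank vector");
  double rho_obs = std::fabs(sxy / std::sqrt(sx * sy));
  std::vector<double> ys = yv;
  std::sort(ys.begin(), ys.end());
  double count = 0.0, total = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (x[i] - mx) * (ys[i] - my);
    double rho = std::fabs(s / std::sqrt(sx * sy));
    if (rho >= rho_obs - 1e-12) count += 1.0;
    total += 1.0;
  } while (std::next_permutation(ys.begin(), ys.end()));
  return count / total;
}
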