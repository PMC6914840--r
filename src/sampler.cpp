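#include <Rcpp.h>
using namespace Rcpp;

// Self-contained adaptive random-walk Metropolis samplers for the two
// single-predictor models. One proposal per coordinate per iteration;
// proposal scales adapt in batches of 50 during warm-up toward a 0.44
// acceptance rate and are frozen afterwards. All randomness comes from R's
// RNG, so draws are bit-reproducible given set.seed() in the caller.

static const int BATCH = 50;

struct Adapt {
  std::vector<double> step;
  std::vector<int> acc;
  int batch_n = 0;

  explicit Adapt(int k, double s0) : step(k, s0), acc(k, 0) {}

  void maybe_update(int iter, int n_warmup) {
    if (iter >= n_warmup || (iter + 1) % BATCH != 0) return;
    ++batch_n;
    double delta = std::min(0.2, 1.0 / std::sqrt((double)batch_n));
    for (size_t j = 0; j < step.size(); ++j) {
      double rate = (double)acc[j] / BATCH;
      step[j] *= std::exp(rate > 0.44 ? delta : -delta);
      acc[j] = 0;
    }
  }
};

static inline double softplus(double z) {
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

// Linear model y = a + b x + eps, eps ~ N(0, sigma^2).
// Priors: b ~ N(prior_loc, prior_scale), a ~ N(0, intercept_scale),
// sigma ~ half-Cauchy(0, sigma_scale), sampled on the log scale.
// The Gaussian likelihood depends on (a, b) only through sufficient
// statistics, so each evaluation is O(1).
class LinearPost {
public:
  double n, Sx, Sy, Sxx, Syy, Sxy;
  double ploc, pscale, ascale, sscale;
  bool sigma_free;

  LinearPost(const NumericVector& x, const NumericVector& y,
             double ploc_, double pscale_, double ascale_, double sscale_,
             bool sigma_free_)
      : ploc(ploc_), pscale(pscale_), ascale(ascale_), sscale(sscale_),
        sigma_free(sigma_free_) {
    n = x.size();
    Sx = Sy = Sxx = Syy = Sxy = 0.0;
    for (int i = 0; i < x.size(); ++i) {
      Sx += x[i]; Sy += y[i];
      Sxx += x[i] * x[i]; Syy += y[i] * y[i]; Sxy += x[i] * y[i];
    }
  }

  double operator()(const std::vector<double>& th) const {
    double a = th[0], b = th[1], t = th[2];
    double sse = Syy - 2.0 * a * Sy - 2.0 * b * Sxy + 2.0 * a * b * Sx +
                 n * a * a + b * b * Sxx;
    double lp = -n * t - 0.5 * std::exp(-2.0 * t) * sse;
    double zb = (b - ploc) / pscale, za = a / ascale;
    lp += -0.5 * zb * zb - 0.5 * za * za;
    if (sigma_free) {
      double s = std::exp(t);
      lp += t - std::log1p((s / sscale) * (s / sscale));  // half-Cauchy + Jacobian
    }
    return lp;
  }
};

// Logistic model logit P(y=1) = a + b x; priors b ~ N(prior_loc,
// prior_scale), a ~ N(0, intercept_scale).
class LogisticPost {
public:
  const NumericVector& x;
  const NumericVector& y;
  double ploc, pscale, ascale;

  LogisticPost(const NumericVector& x_, const NumericVector& y_,
               double ploc_, double pscale_, double ascale_)
      : x(x_), y(y_), ploc(ploc_), pscale(pscale_), ascale(ascale_) {}

  double operator()(const std::vector<double>& th) const {
    double a = th[0], b = th[1];
    double ll = 0.0;
    for (int i = 0; i < x.size(); ++i) {
      double eta = a + b * x[i];
      ll += y[i] * eta - softplus(eta);
    }
    double zb = (b - ploc) / pscale, za = a / ascale;
    return ll - 0.5 * zb * zb - 0.5 * za * za;
  }
};

template <class Post>
static NumericMatrix run_chains(const Post& post, std::vector<double> init,
                                const std::vector<int>& sampled,
                                int n_chains, int n_iter, int n_warmup,
                                int thin, int slope_index) {
  if (thin < 1) thin = 1;
  int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix out(n_keep, n_chains);
  int k = init.size();
  for (int c = 0; c < n_chains; ++c) {
    std::vector<double> th = init;
    for (int j : sampled) th[j] += 0.1 * norm_rand();  // overdispersed starts
    double lp = post(th);
    if (!std::isfinite(lp)) stop("non-finite log-posterior at initialization");
    Adapt ad(k, 0.5);
    for (int it = 0; it < n_iter; ++it) {
      for (int j : sampled) {
        double old = th[j];
        th[j] = old + ad.step[j] * norm_rand();
        double lp_new = post(th);
        if (std::isfinite(lp_new) && std::log(unif_rand()) < lp_new - lp) {
          lp = lp_new;
          ad.acc[j] += 1;
        } else {
          th[j] = old;
        }
      }
      ad.maybe_update(it, n_warmup);
      if (it >= n_warmup && (it - n_warmup) % thin == thin - 1 &&
          (it - n_warmup) / thin < n_keep) {
        out((it - n_warmup) / thin, c) = th[slope_index];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix mcmc_linear(NumericVector x, NumericVector y,
                          double prior_loc, double prior_scale,
                          double intercept_scale, double sigma_scale,
                          int n_chains, int n_iter, int n_warmup, int thin,
                          double sigma_fixed) {
  bool sigma_free = !std::isfinite(sigma_fixed) || sigma_fixed <= 0.0;
  LinearPost post(x, y, prior_loc, prior_scale, intercept_scale, sigma_scale,
                  sigma_free);
  double sy = 1.0;
  if (y.size() > 1) {
    double m = mean(y), v = 0.0;
    for (int i = 0; i < y.size(); ++i) v += (y[i] - m) * (y[i] - m);
    sy = std::sqrt(v / (y.size() - 1));
    if (!(sy > 0.0)) sy = 1.0;
  }
  std::vector<double> init{0.0, 0.0,
                           std::log(sigma_free ? sy : sigma_fixed)};
  std::vector<int> sampled = sigma_free ? std::vector<int>{0, 1, 2}
                                        : std::vector<int>{0, 1};
  return run_chains(post, init, sampled, n_chains, n_iter, n_warmup, thin, 1);
}

// [[Rcpp::export]]
NumericMatrix mcmc_logistic(NumericVector x, NumericVector y,
                            double prior_loc, double prior_scale,
                            double intercept_scale,
                            int n_chains, int n_iter, int n_warmup,
                            int thin) {
  LogisticPost post(x, y, prior_loc, prior_scale, intercept_scale);
  std::vector<double> init{0.0, 0.0};
  std::vector<int> sampled{0, 1};
  return run_chains(post, init, sampled, n_chains, n_iter, n_warmup, thin, 1);
}
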