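#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion (unit diffusion s = 1)
// between absorbing bounds 0 and a, start a*w, drift v, at the LOWER bound.
// Evaluated via the small-time / large-time series expansions with the
// truncation chosen by the standard error bound (tolerance eps on the
// normalized density).
static double wfpt_lower_norm(double u, double w, double eps) {
    // density of normalized process (a = 1, v = 0) at normalized time u
    if (u <= 0.0) return 0.0;
    // number of terms needed, small-time
    double ks = 2.0;
    if (2.0 * eps * std::sqrt(2.0 * M_PI * u) < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
        ks = std::max(ks, std::sqrt(u) + 1.0);
    }
    // number of terms needed, large-time
    double kl = 1.0 / (M_PI * std::sqrt(u));
    if (M_PI * u * eps < 1.0) {
        kl = std::max(std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u)), kl);
    }
    double f = 0.0;
    if (ks < kl) {
        int K = (int) std::ceil(ks);
        for (int k = -((K - 1) / 2); k <= K / 2; ++k) {
            double z = w + 2.0 * k;
            f += z * std::exp(-z * z / (2.0 * u));
        }
        f /= std::sqrt(2.0 * M_PI * u * u * u);
    } else {
        int K = (int) std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
        }
        f *= M_PI;
    }
    return std::max(f, 0.0);
}

// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a, double w,
                               IntegerVector upper, double eps = 1e-10) {
    // upper[i] == 1: density of absorption at the UPPER bound (correct under
    // accuracy coding with v > 0); 0: lower bound. t is decision time (s).
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double ti = t[i];
        if (!std::isfinite(ti) || ti <= 0.0) { out[i] = 0.0; continue; }
        double vv = v, ww = w;
        if (upper[i] == 1) { vv = -v; ww = 1.0 - w; } // reflection
        double u = ti / (a * a);
        double f = wfpt_lower_norm(u, ww, eps);
        out[i] = f / (a * a) * std::exp(-vv * a * ww - vv * vv * ti / 2.0);
    }
    return out;
}

// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(int n, double v, double a, double w, double t0,
                 double dt, double max_t, unsigned int seed) {
    // Euler scheme with Brownian-bridge crossing correction at each step:
    // the probability that the path crossed a bound between two interior
    // points x and y within dt is exp(-2*d1*d2/dt) for bound distances d1,d2.
    std::mt19937_64 rng(seed);
    std::normal_distribution<double> norm(0.0, 1.0);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    NumericVector rt(n);
    IntegerVector upper(n);
    double sdt = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double x = a * w, t = 0.0;
        int hit = -1;
        while (t < max_t) {
            double y = x + v * dt + sdt * norm(rng);
            t += dt;
            if (y <= 0.0) { hit = 0; break; }
            if (y >= a)   { hit = 1; break; }
            double pl = std::exp(-2.0 * x * y / dt);
            double pu = std::exp(-2.0 * (a - x) * (a - y) / dt);
            double uu = unif(rng);
            if (uu < pl) { hit = 0; break; }
            if (uu < pl + pu) { hit = 1; break; }
            x = y;
        }
        if (hit < 0) { // censored at max_t (negligible mass for sane params)
            hit = (x >= a * w) ? 1 : 0;
            t = max_t;
        }
        rt[i] = t + t0;
        upper[i] = hit;
    }
    return List::create(_["rt"] = rt, _["upper"] = upper);
}
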