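#include <Rcpp.h>
using namespace Rcpp;

// log(sinh(y)) for y > 0, stable for arbitrarily large y
static inline double logsinh(double y) {
    return y + log1p(-std::exp(-2.0 * y)) - M_LN2;
}

// \int_0^L v(x; mu) dx with v = u/lambda, i.e. E[N] at lambda = 1.
// Stable form of (1/mu) * [1 - sech(s L/2) cosh(s (L - 2 z)/2)], s = sqrt(mu).
static inline double int_v(double mu, double L, double z) {
    if (mu < 1e-10)
        return 0.5 * z * (L - z);
    double s = std::sqrt(mu);
    double c = std::fabs(0.5 * L - z);           // |L - 2z| / 2 <= L/2
    double g = std::exp(-s * (0.5 * L - c)) *
        (1.0 + std::exp(-2.0 * s * c)) / (1.0 + std::exp(-s * L));
    return (1.0 - g) / mu;
}

// Per-evaluation likelihood terms for the death rate mu:
//   out[0] = sum_i log v(x_i; mu)  over all particles, where
//            a_i = min(x_i, z_i), b_i = L_i - max(x_i, z_i), Lp_i = L_i
//   out[1] = sum_m \int_{0}^{L_m} v(x; mu) dx  over cells (Lg, zg)
// The full log-likelihood is n log(lambda) + out[0] - lambda * out[1].
// [[Rcpp::export]]
NumericVector bdd_mu_terms(double mu, NumericVector a, NumericVector b,
                           NumericVector Lp, NumericVector Lg,
                           NumericVector zg) {
    R_xlen_t n = a.size();
    double slv = 0.0;
    if (mu < 1e-10) {
        for (R_xlen_t i = 0; i < n; ++i)
            slv += std::log(a[i]) + std::log(b[i]) - std::log(Lp[i]);
    } else {
        double s = std::sqrt(mu);
        for (R_xlen_t i = 0; i < n; ++i)
            slv += logsinh(s * a[i]) + logsinh(s * b[i]) - logsinh(s * Lp[i]);
        slv -= 0.5 * static_cast<double>(n) * std::log(mu);
    }
    double siv = 0.0;
    for (R_xlen_t j = 0; j < Lg.size(); ++j)
        siv += int_v(mu, Lg[j], zg[j]);
    return NumericVector::create(slv, siv);
}
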