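// Euler-Maruyama integrator for the delayed-feedback excitatory-
// inhibitory oscillator network.  Delays are handled with a circular
// history buffer of the excitatory potentials; noise uses R's RNG so
// set.seed() on the R side makes runs reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& v, double h, double slope) {
  return 1.0 / (1.0 + arma::exp(-slope * (v - h)));
}

// [[Rcpp::export(name = ".network_sim_cpp")]]
List network_sim_cpp(const arma::mat& W_ee, const arma::mat& W_ei,
                     const arma::mat& W_ie, const arma::mat& W_ii,
                     const arma::mat& W1, const arma::mat& W2,
                     List par, const arma::vec& stim, int n_steps,
                     int burn_steps, bool keep_potentials) {
  const double tau_e = par["tau_e"], tau_i = par["tau_i"];
  const double a = par["a"];
  const double g_ee = par["g_ee"], g_ei = par["g_ei"];
  const double g_ie = par["g_ie"], g_ii = par["g_ii"];
  const double g1 = par["g1"], g2 = par["g2"];
  const double h0 = par["h0"], h1 = par["h1"], h2 = par["h2"];
  const double I_in = par["I_input"];       // I_bias + state input
  const double noise_D = par["noise_D"];
  const double slope = par["sigmoid_slope"];
  const double dt = par["dt"];
  const int d1 = par["d1_steps"], d2 = par["d2_steps"];

  const int N = W_ee.n_rows;
  const int total = burn_steps + n_steps;
  const int hist_len = std::max(std::max(d1, d2), 1) + 1;

  arma::vec Ve(N, arma::fill::zeros), Vi(N, arma::fill::zeros);
  arma::mat hist(N, hist_len, arma::fill::zeros);  // Ve history ring
  arma::vec ecog(n_steps);
  arma::mat out_e, out_i;
  if (keep_potentials) {
    out_e.set_size(N, n_steps);
    out_i.set_size(N, n_steps);
  }
  // Euler-Maruyama noise increment: sqrt(2 D dt) * eta / tau
  const double sde = std::sqrt(2.0 * noise_D * dt) / tau_e;
  const double sdi = std::sqrt(2.0 * noise_D * dt) / tau_i;

  for (int t = 0; t < total; ++t) {
    const int ring = t % hist_len;
    // delayed excitatory potentials (history is zero for t < delay)
    const arma::vec& Ve_d1 = hist.col(((t - d1) % hist_len + hist_len) % hist_len);
    const arma::vec& Ve_d2 = hist.col(((t - d2) % hist_len + hist_len) % hist_len);
    hist.col(ring) = Ve;

    arma::vec fe = sigm(Ve, h0, slope);
    arma::vec fi = sigm(Vi, h0, slope);
    double S = (t >= burn_steps) ? stim(t - burn_steps) : 0.0;

    arma::vec drift_e = a * Ve + g_ee * (W_ee * fe) + g_ie * (W_ie * fi)
      + g1 * (W1 * sigm(Ve_d1, h1, slope))
      + g2 * (W2 * sigm(Ve_d2, h2, slope)) + I_in + S;
    arma::vec drift_i = a * Vi + g_ei * (W_ei * fe) + g_ii * (W_ii * fi) + S;

    arma::vec eta_e(N), eta_i(N);
    if (noise_D > 0) {
      eta_e = as<arma::vec>(rnorm(N));
      eta_i = as<arma::vec>(rnorm(N));
    } else {
      eta_e.zeros();
      eta_i.zeros();
    }

    Ve += (dt / tau_e) * drift_e + sde * eta_e;
    Vi += (dt / tau_i) * drift_i + sdi * eta_i;

    if (!Ve.is_finite() || !Vi.is_finite())
      stop("integration diverged at step %d", t);

    if (t >= burn_steps) {
      const int k = t - burn_steps;
      ecog(k) = arma::mean(Ve + Vi);
      if (keep_potentials) {
        out_e.col(k) = Ve;
        out_i.col(k) = Vi;
      }
    }
  }

  List out = List::create(Named("ecog") = ecog);
  if (keep_potentials) {
    out["V_e"] = out_e;
    out["V_i"] = out_i;
  }
  return out;
}
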