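// Clock-driven core for networks of stochastic adaptive GIF neurons.
//
// Forward Euler on the membrane equation (dt fixed), exact exponential
// decay for spike-triggered kernel state variables and synaptic current
// accumulators, Bernoulli spike sampling with hazard lambda*dt evaluated at
// the start-of-step voltage. After a spike the potential is reset and
// integration restarts immediately; during the absolute refractory period
// the potential evolves but spiking is suppressed.
// Synaptic currents use one exponential accumulator per
// (neuron, tau_syn) pair; spikes are delivered after a fixed transmission
// delay via a ring buffer. All randomness is drawn from R's RNG so that a
// set.seed() on the R side makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct NoiseChannel {
  std::vector<double> next;   // next arrival time (ms), R_PosInf if silent
  std::vector<double> iat;    // mean inter-arrival time (ms)
  NumericVector w;            // jump size per arrival (pA, signed)
  IntegerVector g;            // accumulator group (0-based)
  int on, off;                // active step range [on, off)
  bool started;
};

}  // namespace

// [[Rcpp::export]]
List sim_network_cpp(int n_steps, double dt, int delay_steps,
                     NumericVector Cm, NumericVector gL, NumericVector EL,
                     IntegerVector ref_steps, NumericVector Vreset,
                     NumericVector lam0, NumericVector dV,
                     NumericVector VTstar,
                     NumericMatrix eta_amp, NumericMatrix eta_tau,
                     NumericMatrix gam_amp, NumericMatrix gam_tau,
                     IntegerVector sp, IntegerVector si, NumericVector sw,
                     IntegerVector sg, NumericVector group_tau,
                     List noise_channels,
                     NumericVector stim_amp, int stim_on, int stim_off,
                     int record_every, bool record_VT) {
  const int n = Cm.size();
  const int n_eta = eta_amp.nrow(), n_gam = gam_amp.nrow();
  const int n_grp = group_tau.size();
  if (delay_steps < 1) stop("transmission delay must be at least one step");

  // precomputed decay factors
  std::vector<double> eta_dec(n_eta * n), gam_dec(n_gam * n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < n_eta; ++k)
      eta_dec[k * n + i] = std::exp(-dt / eta_tau(k, i));
    for (int k = 0; k < n_gam; ++k)
      gam_dec[k * n + i] = std::exp(-dt / gam_tau(k, i));
  }
  std::vector<double> grp_dec(n_grp);
  for (int g = 0; g < n_grp; ++g) grp_dec[g] = std::exp(-dt / group_tau[g]);

  // state
  std::vector<double> V(EL.begin(), EL.end());
  std::vector<double> y(static_cast<size_t>(n_grp) * n, 0.0);
  std::vector<double> z_eta(static_cast<size_t>(n_eta) * n, 0.0);
  std::vector<double> z_gam(static_cast<size_t>(n_gam) * n, 0.0);
  std::vector<int> refrac(n, 0);
  std::vector<std::vector<int> > pending(delay_steps + 1);

  // noise channels
  std::vector<NoiseChannel> chans;
  for (int c = 0; c < noise_channels.size(); ++c) {
    List ch = noise_channels[c];
    NoiseChannel nc;
    NumericVector rate = ch["rate"];  // Hz per neuron
    nc.w = ch["w"];
    nc.g = ch["g"];
    nc.on = as<int>(ch["on"]);
    nc.off = as<int>(ch["off"]);
    nc.started = false;
    nc.next.assign(n, R_PosInf);
    nc.iat.resize(n);
    for (int i = 0; i < n; ++i)
      nc.iat[i] = rate[i] > 0 ? 1000.0 / rate[i] : R_PosInf;
    chans.push_back(nc);
  }

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix Vrec(n, n_rec);
  NumericMatrix VTrec(record_VT ? n : 1, record_VT ? n_rec : 1);
  for (int i = 0; i < n; ++i) {
    Vrec(i, 0) = V[i];
    if (record_VT) VTrec(i, 0) = VTstar[i];
  }
  std::vector<double> spike_t;
  std::vector<int> spike_id;

  for (int t = 0; t < n_steps; ++t) {
    const double t_ms = t * dt;
    // deliver recurrent spikes that have completed the transmission delay
    std::vector<int>& slot = pending[t % (delay_steps + 1)];
    for (size_t u = 0; u < slot.size(); ++u) {
      const int j = slot[u];
      for (int k = sp[j]; k < sp[j + 1]; ++k)
        y[static_cast<size_t>(sg[k]) * n + si[k]] += sw[k];
    }
    slot.clear();
    // external Poisson arrivals
    for (size_t c = 0; c < chans.size(); ++c) {
      NoiseChannel& nc = chans[c];
      if (t < nc.on || t >= nc.off) continue;
      if (!nc.started) {
        for (int i = 0; i < n; ++i)
          if (R_finite(nc.iat[i]))
            nc.next[i] = t_ms + R::exp_rand() * nc.iat[i];
        nc.started = true;
      }
      for (int i = 0; i < n; ++i) {
        while (nc.next[i] <= t_ms) {
          y[static_cast<size_t>(nc.g[i]) * n + i] += nc.w[i];
          nc.next[i] += R::exp_rand() * nc.iat[i];
        }
      }
    }
    const bool stim_now = (t >= stim_on && t < stim_off);
    const bool rec = ((t + 1) % record_every) == 0;
    const int r = (t + 1) / record_every;
    for (int i = 0; i < n; ++i) {
      double I = 0.0;
      for (int g = 0; g < n_grp; ++g) I += y[static_cast<size_t>(g) * n + i];
      if (stim_now) I += stim_amp[i];
      double esum = 0.0, gsum = 0.0;
      for (int k = 0; k < n_eta; ++k) esum += z_eta[static_cast<size_t>(k) * n + i];
      for (int k = 0; k < n_gam; ++k) gsum += z_gam[static_cast<size_t>(k) * n + i];
      if (refrac[i] > 0) {
        // absolutely refractory: no spike, but integration has restarted
        --refrac[i];
        V[i] += dt / Cm[i] * (-gL[i] * (V[i] - EL[i]) - esum + I);
      } else {
        const double lam = lam0[i] * std::exp((V[i] - (VTstar[i] + gsum)) / dV[i]);
        double hazard = lam * dt;
        if (hazard > 1e3) hazard = 1e3;  // probability saturates at 1
        if (unif_rand() < -std::expm1(-hazard)) {
          spike_t.push_back(t_ms);
          spike_id.push_back(i + 1);
          V[i] = Vreset[i];
          refrac[i] = ref_steps[i];
          for (int k = 0; k < n_eta; ++k)
            z_eta[static_cast<size_t>(k) * n + i] += eta_amp(k, i);
          for (int k = 0; k < n_gam; ++k)
            z_gam[static_cast<size_t>(k) * n + i] += gam_amp(k, i);
          if (sp[i + 1] > sp[i])
            pending[(t + delay_steps) % (delay_steps + 1)].push_back(i);
        } else {
          V[i] += dt / Cm[i] * (-gL[i] * (V[i] - EL[i]) - esum + I);
        }
      }
      // advance kernel state to t + dt
      double g2 = 0.0;
      for (int k = 0; k < n_eta; ++k)
        z_eta[static_cast<size_t>(k) * n + i] *= eta_dec[static_cast<size_t>(k) * n + i];
      for (int k = 0; k < n_gam; ++k) {
        z_gam[static_cast<size_t>(k) * n + i] *= gam_dec[static_cast<size_t>(k) * n + i];
        g2 += z_gam[static_cast<size_t>(k) * n + i];
      }
      if (rec) {
        Vrec(i, r) = V[i];
        if (record_VT) VTrec(i, r) = VTstar[i] + g2;
      }
    }
    // advance synaptic accumulators to t + dt
    for (int g = 0; g < n_grp; ++g) {
      const double d = grp_dec[g];
      double* yg = &y[static_cast<size_t>(g) * n];
      for (int i = 0; i < n; ++i) yg[i] *= d;
    }
  }

  return List::create(_["spike_t"] = wrap(spike_t),
                      _["spike_id"] = wrap(spike_id),
                      _["V"] = Vrec,
                      _["VT"] = record_VT ? SEXP(VTrec) : R_NilValue,
                      _["record_dt"] = record_every * dt);
}

// Gain-function estimation: a group of independent, initially non-adapted
// GIF neurons driven by a common-mean current with independent filtered
// (Ornstein-Uhlenbeck) noise whose stationary standard deviation is
// sigma_I. Returns spike counts per neuron and 10 ms (window_steps) window.

// [[Rcpp::export]]
IntegerMatrix sim_gain_cpp(int n_neurons, int n_steps, double dt,
                           double Cm, double gL, double EL, int ref_steps,
                           double Vreset, double lam0, double dV,
                           double VTstar,
                           NumericVector eta_amp, NumericVector eta_tau,
                           NumericVector gam_amp, NumericVector gam_tau,
                           double Imean, double sigmaI, double tau_alpha,
                           int window_steps) {
  const int n_eta = eta_amp.size(), n_gam = gam_amp.size();
  const int n_win = n_steps / window_steps;
  IntegerMatrix counts(n_neurons, n_win);
  std::vector<double> eta_dec(n_eta), gam_dec(n_gam);
  for (int k = 0; k < n_eta; ++k) eta_dec[k] = std::exp(-dt / eta_tau[k]);
  for (int k = 0; k < n_gam; ++k) gam_dec[k] = std::exp(-dt / gam_tau[k]);
  // OU process x with stationary sd 1: x' = x e^{-dt/tau} + N(0, s_inc)
  const double ou_dec = std::exp(-dt / tau_alpha);
  const double ou_sd = std::sqrt(1.0 - ou_dec * ou_dec);
  for (int i = 0; i < n_neurons; ++i) {
    double V = EL, x = norm_rand();
    std::vector<double> z_eta(n_eta, 0.0), z_gam(n_gam, 0.0);
    int refrac = 0;
    for (int t = 0; t < n_steps; ++t) {
      const double I = Imean + sigmaI * x;
      double esum = 0.0, gsum = 0.0;
      for (int k = 0; k < n_eta; ++k) esum += z_eta[k];
      for (int k = 0; k < n_gam; ++k) gsum += z_gam[k];
      if (refrac > 0) {
        --refrac;
        V += dt / Cm * (-gL * (V - EL) - esum + I);
      } else {
        const double lam = lam0 * std::exp((V - (VTstar + gsum)) / dV);
        double hazard = lam * dt;
        if (hazard > 1e3) hazard = 1e3;
        if (unif_rand() < -std::expm1(-hazard)) {
          ++counts(i, t / window_steps);
          V = Vreset;
          refrac = ref_steps;
          for (int k = 0; k < n_eta; ++k) z_eta[k] += eta_amp[k];
          for (int k = 0; k < n_gam; ++k) z_gam[k] += gam_amp[k];
        } else {
          V += dt / Cm * (-gL * (V - EL) - esum + I);
        }
      }
      for (int k = 0; k < n_eta; ++k) z_eta[k] *= eta_dec[k];
      for (int k = 0; k < n_gam; ++k) z_gam[k] *= gam_dec[k];
      x = x * ou_dec + ou_sd * norm_rand();
    }
  }
  return counts;
}

// The injected current of sim_gain_cpp, exposed for calibration checks:
// returns Imean + sigmaI * x_t sampled at every step.

// [[Rcpp::export]]
NumericVector ou_current_cpp(int n_steps, double dt, double Imean,
                             double sigmaI, double tau_alpha) {
  NumericVector out(n_steps);
  const double ou_dec = std::exp(-dt / tau_alpha);
  const double ou_sd = std::sqrt(1.0 - ou_dec * ou_dec);
  double x = norm_rand();
  for (int t = 0; t < n_steps; ++t) {
    out[t] = Imean + sigmaI * x;
    x = x * ou_dec + ou_sd * norm_rand();
  }
  return out;
}
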