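#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weight-dependent learning rates.  The asymmetric (multiplicative) profile
// potentiates weak and depresses strong synapses; the symmetric profile peaks
// at mid-range and vanishes at both bounds; the hybrid profile is the convex
// combination alpha * SR + (1 - alpha) * AR.  alpha = 0 and alpha = 1
// reproduce AR and SR bit-for-bit (0 * x + 1 * y == y in IEEE arithmetic for
// finite x, y).
static inline double eps_sr(double w, double wmin, double wmax) {
  return 2.0 * std::min(wmax - w, w - wmin);
}

static inline double eps_plus(double w, double alpha, double wmin, double wmax) {
  return alpha * eps_sr(w, wmin, wmax) + (1.0 - alpha) * (wmax - w);
}

static inline double eps_minus(double w, double alpha, double wmin, double wmax) {
  return alpha * eps_sr(w, wmin, wmax) + (1.0 - alpha) * (w - wmin);
}

static inline double clipw(double w, double wmin, double wmax) {
  if (w < wmin) return wmin;
  if (w > wmax) return wmax;
  return w;
}

//' @noRd
// [[Rcpp::export]]
List cpp_run_network(const IntegerMatrix mask, const NumericMatrix W0,
                     const IntegerVector pre_neuron, const IntegerVector pre_step,
                     const IntegerVector force_neuron, const IntegerVector force_step,
                     int n_steps, bool plastic, List lif, List stdp,
                     double alpha, Nullable<List> state0) {
  const int n_in  = mask.nrow();
  const int n_out = mask.ncol();

  const double C        = as<double>(lif["C"]);
  const double gL       = as<double>(lif["g_L"]);
  const double EL       = as<double>(lif["E_L"]);
  const double Esyn     = as<double>(lif["E_syn"]);
  const double Eth      = as<double>(lif["E_threshold"]);
  const double tau_syn  = as<double>(lif["tau_syn"]);
  const double c_syn    = as<double>(lif["c_syn"]);
  const double sigma    = as<double>(lif["noise_sigma"]);
  const double dt       = as<double>(lif["dt"]);

  const double k_plus    = as<double>(stdp["k_plus"]);
  const double k_minus   = as<double>(stdp["k_minus"]);
  const double tau_plus  = as<double>(stdp["tau_plus"]);
  const double tau_minus = as<double>(stdp["tau_minus"]);
  const double wmin      = as<double>(stdp["w_min"]);
  const double wmax      = as<double>(stdp["w_max"]);

  const double dec_plus  = std::exp(-dt / tau_plus);
  const double dec_minus = std::exp(-dt / tau_minus);

  // adjacency lists from the fixed connectivity mask
  std::vector< std::vector<int> > out_of_in(n_in);   // outputs driven by input i
  std::vector< std::vector<int> > in_of_out(n_out);  // inputs feeding output j
  for (int i = 0; i < n_in; ++i)
    for (int j = 0; j < n_out; ++j)
      if (mask(i, j)) { out_of_in[i].push_back(j); in_of_out[j].push_back(i); }

  NumericMatrix W = clone(W0);

  std::vector<double> V(n_out, EL), g(n_out, 0.0);
  std::vector<double> x(n_in, 0.0);   // presynaptic LTP trace (tau_plus)
  std::vector<double> y(n_out, 0.0);  // postsynaptic LTD trace (tau_minus)
  if (state0.isNotNull()) {
    List st(state0);
    NumericVector V0 = st["V"], g0 = st["g"], x0 = st["x"], y0 = st["y"];
    if (V0.size() != n_out || g0.size() != n_out ||
        x0.size() != n_in || y0.size() != n_out)
      stop("carried state has wrong dimensions");
    for (int j = 0; j < n_out; ++j) { V[j] = V0[j]; g[j] = g0[j]; y[j] = y0[j]; }
    for (int i = 0; i < n_in; ++i) x[i] = x0[i];
  }
  std::vector<double> drive(n_out, 0.0);
  std::vector<char> pre_now(n_in, 0);

  std::vector<int> out_nrn, out_stp;
  const int n_events = pre_neuron.size();
  const int n_force = force_neuron.size();
  int ev = 0, fv = 0;
  std::vector<int> cur_pre;
  std::vector<char> fired(n_out, 0);

  for (int t = 0; t < n_steps; ++t) {
    // presynaptic spikes arriving at this step (events sorted by step)
    cur_pre.clear();
    while (ev < n_events && pre_step[ev] == t) {
      const int i = pre_neuron[ev];
      cur_pre.push_back(i);
      pre_now[i] = 1;
      ++ev;
    }

    if (plastic) {
      for (int i = 0; i < n_in; ++i)  x[i] *= dec_plus;
      for (int j = 0; j < n_out; ++j) y[j] *= dec_minus;
      // LTD from pairings with earlier postsynaptic spikes (dt_pair < 0)
      for (size_t a = 0; a < cur_pre.size(); ++a) {
        const int i = cur_pre[a];
        const std::vector<int>& js = out_of_in[i];
        for (size_t b = 0; b < js.size(); ++b) {
          const int j = js[b];
          double w = W(i, j);
          w += eps_minus(w, alpha, wmin, wmax) * k_minus * y[j];
          W(i, j) = clipw(w, wmin, wmax);
        }
      }
    }

    // synaptic drive from this step's input spikes
    std::fill(drive.begin(), drive.end(), 0.0);
    for (size_t a = 0; a < cur_pre.size(); ++a) {
      const int i = cur_pre[a];
      const std::vector<int>& js = out_of_in[i];
      for (size_t b = 0; b < js.size(); ++b) drive[js[b]] += W(i, js[b]);
    }

    // coupled forward Euler: the voltage update sees the conductance from
    // the start of the step
    for (int j = 0; j < n_out; ++j) {
      const double g_old = g[j];
      g[j] = g_old + dt * (-g_old / tau_syn + c_syn * drive[j]);
      const double noise = (sigma > 0.0) ? sigma * R::norm_rand() : 0.0;
      double v = V[j] + (dt / C) * (gL * (EL - V[j]) +
                                    g_old * (Esyn - V[j]) + noise);
      V[j] = v;
      if (!std::isfinite(v)) stop("membrane voltage diverged (NaN/Inf)");
      if (v >= Eth) {
        V[j] = EL;  // immediate spike and reset within the step
        fired[j] = 1;
      }
    }

    // externally forced postsynaptic spikes (background drive of the output
    // layer); a neuron that already fired this step is not duplicated
    while (fv < n_force && force_step[fv] == t) {
      const int j = force_neuron[fv];
      if (!fired[j]) { fired[j] = 1; V[j] = EL; }
      ++fv;
    }

    for (int j = 0; j < n_out; ++j) {
      if (!fired[j]) continue;
      fired[j] = 0;
      out_nrn.push_back(j);
      out_stp.push_back(t);
      if (plastic) {
        const std::vector<int>& is = in_of_out[j];
        for (size_t b = 0; b < is.size(); ++b) {
          const int i = is[b];
          double w = W(i, j);
          // LTP from earlier presynaptic spikes (x excludes this step)
          w = clipw(w + eps_plus(w, alpha, wmin, wmax) * k_plus * x[i],
                    wmin, wmax);
          // simultaneous pre/post spikes: dt_pair = 0 falls in the LTD branch
          if (pre_now[i]) {
            w = clipw(w + eps_minus(w, alpha, wmin, wmax) * k_minus,
                      wmin, wmax);
          }
          W(i, j) = w;
        }
        y[j] += 1.0;
      }
    }

    if (plastic)
      for (size_t a = 0; a < cur_pre.size(); ++a) x[cur_pre[a]] += 1.0;
    for (size_t a = 0; a < cur_pre.size(); ++a) pre_now[cur_pre[a]] = 0;
  }

  return List::create(_["out_neuron"] = wrap(out_nrn),
                      _["out_step"]   = wrap(out_stp),
                      _["W"]          = W,
                      _["state"]      = List::create(_["V"] = wrap(V),
                                                     _["g"] = wrap(g),
                                                     _["x"] = wrap(x),
                                                     _["y"] = wrap(y)));
}

// Apply the trace-based STDP updates to a fixed pair of pre/post spike
// rasters, without membrane dynamics.  Event ordering within a step is
// identical to cpp_run_network: trace decay, LTD at pre spikes (earlier
// posts), then post spikes in ascending neuron order (LTP from earlier
// pres, coincident-pair LTD, post-trace increment), then pre-trace
// increments.  Given the rasters recorded from a plastic run, this replay
// reproduces the run's final weights bit-for-bit.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_stdp_trace(const IntegerMatrix mask, const NumericMatrix W0,
                             const IntegerVector pre_neuron, const IntegerVector pre_step,
                             const IntegerVector post_neuron, const IntegerVector post_step,
                             int n_steps, List stdp, double alpha, double dt) {
  const int n_in  = mask.nrow();
  const int n_out = mask.ncol();
  const double k_plus    = as<double>(stdp["k_plus"]);
  const double k_minus   = as<double>(stdp["k_minus"]);
  const double tau_plus  = as<double>(stdp["tau_plus"]);
  const double tau_minus = as<double>(stdp["tau_minus"]);
  const double wmin      = as<double>(stdp["w_min"]);
  const double wmax      = as<double>(stdp["w_max"]);
  const double dec_plus  = std::exp(-dt / tau_plus);
  const double dec_minus = std::exp(-dt / tau_minus);

  std::vector< std::vector<int> > out_of_in(n_in);
  std::vector< std::vector<int> > in_of_out(n_out);
  for (int i = 0; i < n_in; ++i)
    for (int j = 0; j < n_out; ++j)
      if (mask(i, j)) { out_of_in[i].push_back(j); in_of_out[j].push_back(i); }

  NumericMatrix W = clone(W0);
  std::vector<double> x(n_in, 0.0), y(n_out, 0.0);
  std::vector<char> pre_now(n_in, 0);
  int ev_pre = 0, ev_post = 0;
  const int n_pre = pre_neuron.size(), n_post = post_neuron.size();
  std::vector<int> cur_pre, cur_post;

  for (int t = 0; t < n_steps; ++t) {
    cur_pre.clear(); cur_post.clear();
    while (ev_pre < n_pre && pre_step[ev_pre] == t) {
      cur_pre.push_back(pre_neuron[ev_pre]);
      pre_now[pre_neuron[ev_pre]] = 1;
      ++ev_pre;
    }
    while (ev_post < n_post && post_step[ev_post] == t) {
      cur_post.push_back(post_neuron[ev_post]);
      ++ev_post;
    }
    for (int i = 0; i < n_in; ++i)  x[i] *= dec_plus;
    for (int j = 0; j < n_out; ++j) y[j] *= dec_minus;
    for (size_t a = 0; a < cur_pre.size(); ++a) {
      const int i = cur_pre[a];
      const std::vector<int>& js = out_of_in[i];
      for (size_t b = 0; b < js.size(); ++b) {
        const int j = js[b];
        double w = W(i, j);
        w += eps_minus(w, alpha, wmin, wmax) * k_minus * y[j];
        W(i, j) = clipw(w, wmin, wmax);
      }
    }
    for (size_t a = 0; a < cur_post.size(); ++a) {
      const int j = cur_post[a];
      const std::vector<int>& is = in_of_out[j];
      for (size_t b = 0; b < is.size(); ++b) {
        const int i = is[b];
        double w = W(i, j);
        w = clipw(w + eps_plus(w, alpha, wmin, wmax) * k_plus * x[i], wmin, wmax);
        if (pre_now[i])
          w = clipw(w + eps_minus(w, alpha, wmin, wmax) * k_minus, wmin, wmax);
        W(i, j) = w;
      }
      y[j] += 1.0;
    }
    for (size_t a = 0; a < cur_pre.size(); ++a) x[cur_pre[a]] += 1.0;
    for (size_t a = 0; a < cur_pre.size(); ++a) pre_now[cur_pre[a]] = 0;
  }
  return W;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_single_synapse(int n_trials, int n_steps, double p_spike,
                                 List stdp, double alpha, double dt) {
  const double k_plus    = as<double>(stdp["k_plus"]);
  const double k_minus   = as<double>(stdp["k_minus"]);
  const double tau_plus  = as<double>(stdp["tau_plus"]);
  const double tau_minus = as<double>(stdp["tau_minus"]);
  const double wmin      = as<double>(stdp["w_min"]);
  const double wmax      = as<double>(stdp["w_max"]);

  NumericVector out(n_trials);

  for (int trial = 0; trial < n_trials; ++trial) {
    double w = wmin + (wmax - wmin) * R::unif_rand();
    if (p_spike <= 0.0) { out[trial] = w; continue; }

    double xtr = 0.0, ytr = 0.0;  // pre / post traces
    int t_last = 0;
    // geometric gaps between Bernoulli(p_spike) successes on the ms grid
    int t_pre  = (int)R::rgeom(p_spike);
    int t_post = (int)R::rgeom(p_spike);

    while (t_pre < n_steps || t_post < n_steps) {
      const int t = std::min(t_pre, t_post);
      if (t >= n_steps) break;
      const double gap = (double)(t - t_last) * dt;
      xtr *= std::exp(-gap / tau_plus);
      ytr *= std::exp(-gap / tau_minus);
      t_last = t;

      const bool pre  = (t_pre == t);
      const bool post = (t_post == t);
      if (pre)  // LTD from earlier postsynaptic spikes
        w = clipw(w + eps_minus(w, alpha, wmin, wmax) * k_minus * ytr, wmin, wmax);
      if (post) // LTP from earlier presynaptic spikes
        w = clipw(w + eps_plus(w, alpha, wmin, wmax) * k_plus * xtr, wmin, wmax);
      if (pre && post) // coincident pair: dt_pair = 0 is LTD
        w = clipw(w + eps_minus(w, alpha, wmin, wmax) * k_minus, wmin, wmax);

      if (pre)  { xtr += 1.0; t_pre  += 1 + (int)R::rgeom(p_spike); }
      if (post) { ytr += 1.0; t_post += 1 + (int)R::rgeom(p_spike); }
    }
    out[trial] = w;
  }
  return out;
}
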