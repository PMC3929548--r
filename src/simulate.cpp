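// Core fixed-step integrator for conductance-based pulse-coupled networks.
//
// Between synaptic events the conductances decay exactly (closed form) and
// the voltage is advanced by second-order Runge-Kutta (Heun).  Feedforward
// Poisson events are applied at their exact times by splitting the step at
// event times; recurrent spikes detected during a step take effect on their
// targets from the end of that step, with the conductance jump decayed
// exactly from the interpolated spike time.  Threshold crossings are located
// by linear interpolation inside the sub-step, the voltage is reset and then
// clamped for an absolute refractory period.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  double gL, EL, EE, EI, Vth, Vreset, tauE, tauI, tauref;
  double deltaT, VT, Vcut;
  int kind;            // 0 = IF, 1 = EIF
  double thresh;       // firing threshold actually used
};

inline double dVdt(double V, double GE, double GI, const Params& P) {
  double dv = -P.gL * (V - P.EL) - GE * (V - P.EE) - GI * (V - P.EI);
  if (P.kind == 1) {
    double arg = (V - P.VT) / P.deltaT;
    if (arg > 40.0) arg = 40.0;  // spike current saturates; crossing of Vcut ends the step anyway
    dv += P.gL * P.deltaT * std::exp(arg);
  }
  return dv;
}

struct Neuron {
  double V, GE, GI;
  double refr_until;
  std::size_t ev_ptr;
  std::vector<double> spikes;
};

// Advance one neuron over [a, b] with no synaptic event strictly inside.
// Conductance state is kept at the moving position; spikes are recorded.
inline void advance_segment(Neuron& nrn, double a, double b, const Params& P) {
  while (b - a > 1e-12) {
    if (nrn.refr_until >= b) {
      double h = b - a;
      nrn.GE *= std::exp(-h / P.tauE);
      nrn.GI *= std::exp(-h / P.tauI);
      nrn.V = P.Vreset;
      a = b;
    } else if (nrn.refr_until > a) {
      double h = nrn.refr_until - a;
      nrn.GE *= std::exp(-h / P.tauE);
      nrn.GI *= std::exp(-h / P.tauI);
      nrn.V = P.Vreset;
      a = nrn.refr_until;
    } else {
      double h = b - a;
      double geh = std::exp(-h / P.tauE), gih = std::exp(-h / P.tauI);
      double k1 = dVdt(nrn.V, nrn.GE, nrn.GI, P);
      double k2 = dVdt(nrn.V + h * k1, nrn.GE * geh, nrn.GI * gih, P);
      double Vn = nrn.V + 0.5 * h * (k1 + k2);
      if (!std::isfinite(Vn))
        stop("non-finite membrane potential during integration (t ~ %f ms)", a);
      if (Vn >= P.thresh) {
        double frac = (P.thresh - nrn.V) / (Vn - nrn.V);
        if (frac < 0.0) frac = 0.0;
        if (frac > 1.0) frac = 1.0;
        double tspike = a + frac * h;
        nrn.spikes.push_back(tspike);
        nrn.GE *= std::exp(-(tspike - a) / P.tauE);
        nrn.GI *= std::exp(-(tspike - a) / P.tauI);
        nrn.V = P.Vreset;
        nrn.refr_until = tspike + P.tauref;
        a = tspike;
      } else {
        nrn.V = Vn;
        nrn.GE *= geh;
        nrn.GI *= gih;
        a = b;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(NumericMatrix W, LogicalVector is_exc,
                     List ff_times, List ff_strengths,
                     List par, double duration, double dt, double fs,
                     NumericVector v0) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("coupling matrix must be square");

  Params P;
  P.gL = as<double>(par["g_L"]);     P.EL = as<double>(par["E_L"]);
  P.EE = as<double>(par["E_E"]);     P.EI = as<double>(par["E_I"]);
  P.Vth = as<double>(par["V_th"]);   P.Vreset = as<double>(par["V_reset"]);
  P.tauE = as<double>(par["tau_E"]); P.tauI = as<double>(par["tau_I"]);
  P.tauref = as<double>(par["tau_ref"]);
  P.deltaT = as<double>(par["delta_T"]);
  P.VT = as<double>(par["V_T"]);     P.Vcut = as<double>(par["V_cut"]);
  P.kind = as<int>(par["kind"]);
  if (P.kind == 1 && P.deltaT < 1e-8) P.kind = 0;  // EIF degenerates to IF
  P.thresh = (P.kind == 1) ? P.Vcut : P.Vth;

  const long n_steps = (long) std::floor(duration / dt + 0.5);
  const int steps_per_win = (int) std::floor(1.0 / (fs * dt) + 0.5);
  if (std::fabs(steps_per_win * fs * dt - 1.0) > 1e-8)
    stop("1/(fs*dt) must be an integer number of integration steps");
  const long n_samples = n_steps / steps_per_win;

  std::vector<Neuron> nrn(n);
  std::vector<const double*> ev_t(n), ev_s(n);
  std::vector<std::size_t> ev_n(n);
  for (int i = 0; i < n; ++i) {
    nrn[i].V = v0[i];
    nrn[i].GE = 0.0; nrn[i].GI = 0.0;
    nrn[i].refr_until = -1.0;
    nrn[i].ev_ptr = 0;
    NumericVector t = ff_times[i], s = ff_strengths[i];
    if (t.size() != s.size()) stop("event times/strengths length mismatch");
    ev_t[i] = t.begin(); ev_s[i] = s.begin(); ev_n[i] = t.size();
    // keep the R vectors alive: ff_times/ff_strengths are protected via List
  }

  NumericMatrix volt(n_samples, n);
  std::vector<double> acc(n, 0.0);
  std::vector<int> step_spiker;           // which neurons spiked this step
  long win_step = 0, win_idx = 0;

  for (long step = 0; step < n_steps; ++step) {
    const double t0 = step * dt, t1 = t0 + dt;
    step_spiker.clear();
    for (int i = 0; i < n; ++i) {
      Neuron& N = nrn[i];
      std::size_t before = N.spikes.size();
      double Vb = N.V;
      double cur = t0;
      while (N.ev_ptr < ev_n[i] && ev_t[i][N.ev_ptr] <= t1) {
        double te = ev_t[i][N.ev_ptr];
        if (te > cur) advance_segment(N, cur, te, P), cur = te;
        N.GE += ev_s[i][N.ev_ptr];  // feedforward drive is excitatory
        ++N.ev_ptr;
      }
      if (t1 > cur) advance_segment(N, cur, t1, P);
      if (N.spikes.size() > before) step_spiker.push_back(i);
      acc[i] += 0.5 * (Vb + N.V);   // trapezoidal window average
    }
    // recurrent propagation: jumps take effect at the step end, decayed
    // exactly from the interpolated spike time
    for (std::size_t k = 0; k < step_spiker.size(); ++k) {
      int j = step_spiker[k];
      double ts = nrn[j].spikes.back();
      for (int i = 0; i < n; ++i) {
        double w = W(j, i);
        if (w > 0.0) {
          if (is_exc[j]) nrn[i].GE += w * std::exp(-(t1 - ts) / P.tauE);
          else           nrn[i].GI += w * std::exp(-(t1 - ts) / P.tauI);
        }
      }
    }
    if (++win_step == steps_per_win) {
      for (int i = 0; i < n; ++i) {
        volt(win_idx, i) = acc[i] / steps_per_win;
        acc[i] = 0.0;
      }
      win_step = 0;
      ++win_idx;
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = wrap(nrn[i].spikes);
  return List::create(_["voltages"] = volt, _["spikes"] = spk,
                      _["n_steps"] = (double) n_steps);
}
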