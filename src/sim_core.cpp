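// Network integration core: 7 dynamic variables per cell (V, h, c, d, e, f, t)
// plus one synaptic gate s per cell when the inhibitory loop is active.
// Embedded Verner 6(5) pair with absolute-error step control; steps never
// straddle frame-recording times, inhibitory-loop check times or transmitter
// pulse edges, so the right-hand side is smooth within every accepted step.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CellConst {
  double Cm, gl, Vl, gNa, gNap, gKd, gKs, gh, VNa, VK, Vh, rho, ac_pref;
};

// u/(1 - exp(-0.1 u)) has a removable singularity at u = 0; second-order
// Taylor expansion used for |u| < 1e-6.
inline double ratefun(double pref, double u) {
  if (std::fabs(u) < 1e-6) return pref * 10.0 * (1.0 + 0.05 * u);
  return pref * u / (1.0 - std::exp(-0.1 * u));
}

inline double gam(double X, double Y, double Z) {
  return 1.0 / (1.0 + std::exp(-(X + Y) / Z));
}

struct ILConf {
  bool on = false;
  double window, delay, refractory, sync_fraction;
  double gsyn, Esyn, alpha, beta, Tconc, Tdur, check_dt;
};

// Full right-hand side over the lattice.  y layout: blocks of length N in
// the order V, h, c, d, e, f, t, s.
void rhs(const std::vector<double>& y, std::vector<double>& dy,
         int N, const int* nbr, const int* deg, int K, double g_c,
         const CellConst& P, const double* Iinj, const double* sigma,
         double ramp_I, const double* Tval, const ILConf& il) {
  const double* V = y.data();
  const double* h = V + N;
  const double* c = V + 2 * N;
  const double* d = V + 3 * N;
  const double* e = V + 4 * N;
  const double* f = V + 5 * N;
  const double* tg = V + 6 * N;
  const double* s = V + 7 * N;
  double* dV = dy.data();
  double* dh = dV + N;
  double* dc = dV + 2 * N;
  double* dd = dV + 3 * N;
  double* de = dV + 4 * N;
  double* df = dV + 5 * N;
  double* dt_ = dV + 6 * N;
  double* ds = dV + 7 * N;

  for (int i = 0; i < N; ++i) {
    const double v = V[i];
    const double sg = sigma[i];

    // I_Na kinetics (m instantaneous)
    const double am = ratefun(0.1, v + 30.0 - sg);
    const double bm = 4.0 * std::exp((-v - 55.0 + sg) / 18.0);
    const double minf = am / (am + bm);
    const double ah = 1.99 * std::exp((-v - 44.0 + sg) / 20.0);
    const double bh = 28.57 / (1.0 + std::exp(-0.1 * (v + 14.0 - sg)));
    // I_Nap (instantaneous)
    const double ninf = gam(v, 51.0, 5.0);
    // I_Kd
    const double ac = ratefun(P.ac_pref, v + 34.0 - sg);
    const double bc = 3.57 * std::exp((-v - 44.0 + sg) / 80.0);
    // I_Ks
    const double dinf = gam(v, 34.0, 6.5);
    const double einf = gam(-v, -65.0, 6.6);
    const double taue = 200.0 + 220.0 * gam(v, 71.6, 6.85);
    const double finf = einf;
    const double tauf = 200.0 + 3200.0 * gam(v, 63.6, 4.0);
    // I_h
    const double tinf = gam(-v, -45.0, 5.5);
    const double taut = 1.0 / (std::exp(-14.59 - 0.089 * v) +
                               std::exp(-1.87 + 0.0701 * v));

    const double INa = P.gNa * minf * minf * minf * h[i] * (v - P.VNa);
    const double INap = P.gNap * ninf * (v - P.VNa);
    const double IKd = P.gKd * c[i] * c[i] * c[i] * c[i] * (v - P.VK);
    const double IKs = P.gKs * d[i] * (P.rho * e[i] + (1.0 - P.rho) * f[i]) *
                       (v - P.VK);
    const double Ih = P.gh * tg[i] * (v - P.Vh);
    const double Il = P.gl * (v - P.Vl);

    double Ielec = 0.0;
    if (g_c > 0.0) {
      double acc = 0.0;
      const int* nb = nbr + (size_t)i * K;
      for (int q = 0; q < K; ++q)
        if (nb[q] >= 0) acc += V[nb[q]];
      Ielec = g_c * (deg[i] * v - acc);
    }

    double Isyn = 0.0;
    if (il.on) {
      Isyn = il.gsyn * s[i] * (v - il.Esyn);
      ds[i] = il.alpha * Tval[i] * (1.0 - s[i]) - il.beta * s[i];
    }

    dV[i] = (-INa - INap - IKd - IKs - Ih - Il + Iinj[i] + ramp_I -
             Ielec - Isyn) / P.Cm;
    dh[i] = (ah / (ah + bh) - h[i]) * (ah + bh);
    dc[i] = (ac / (ac + bc) - c[i]) * (ac + bc);
    dd[i] = (dinf - d[i]) / 50.0;
    de[i] = (einf - e[i]) / taue;
    df[i] = (finf - f[i]) / tauf;
    dt_[i] = (tinf - tg[i]) / taut;
  }
}

} // namespace

// Single-cell right-hand side, exposed so the R-level cell_derivative()
// (the documented reference implementation) can be cross-checked against
// the engine.
// [[Rcpp::export(name = ".cell_rhs_cpp")]]
NumericVector cell_rhs_cpp(NumericVector state, NumericVector consts,
                           double sigma, double I_inj,
                           double I_elec, double I_syn) {
  CellConst P{consts["C_m"], consts["g_l"], consts["V_l"], consts["gbar_Na"],
              consts["gbar_Nap"], consts["gbar_Kd"], consts["gbar_Ks"],
              consts["gbar_h"], consts["V_Na"], consts["V_K"], consts["V_h"],
              consts["rho"], consts["alpha_c_pref"]};
  int nbr1 = -1, deg1 = 0;
  std::vector<double> y(8, 0.0), dy(8, 0.0);
  for (int k = 0; k < 7; ++k) y[k] = state[k];
  double Ii = I_inj - I_elec - I_syn; // fold external currents into the drive
  double sg = sigma, Tv = 0.0;
  ILConf il;
  rhs(y, dy, 1, &nbr1, &deg1, 1, 0.0, P, &Ii, &sg, 0.0, &Tv, il);
  return NumericVector(dy.begin(), dy.begin() + 7);
}

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(IntegerMatrix nbr0,         // N x K neighbor indices, 1-based, 0 = none
                     double g_c,
                     NumericVector consts,       // named cell constants
                     NumericMatrix y0,           // N x 7 initial states
                     NumericMatrix Iinj_epochs,  // n_epoch x N
                     NumericMatrix sigma_epochs, // n_epoch x N
                     NumericVector epoch_start,  // ms, first must be 0
                     double ramp_rate,           // uA/cm^2 per ms, added to all cells
                     double duration, double max_error, double dt_max,
                     double dt_record, double spike_threshold,
                     double spike_rearm,
                     List il_conf,               // empty list = loop disabled
                     List il_sense,              // per IF unit: sensed IO cells (1-based)
                     List il_feedback,           // per IF unit: feedback targets (1-based)
                     bool record_full) {         // record all 7 variables per cell
  const int N = y0.nrow();
  const int K = nbr0.ncol();
  std::vector<int> nbr((size_t)N * K);
  std::vector<int> deg(N, 0);
  for (int i = 0; i < N; ++i)
    for (int q = 0; q < K; ++q) {
      nbr[(size_t)i * K + q] = nbr0(i, q) - 1;
      if (nbr0(i, q) > 0) ++deg[i];
    }

  CellConst P{consts["C_m"], consts["g_l"], consts["V_l"], consts["gbar_Na"],
              consts["gbar_Nap"], consts["gbar_Kd"], consts["gbar_Ks"],
              consts["gbar_h"], consts["V_Na"], consts["V_K"], consts["V_h"],
              consts["rho"], consts["alpha_c_pref"]};

  ILConf il;
  std::vector<std::vector<int>> sense, feedback;
  if (il_conf.size() > 0) {
    il.on = true;
    il.window = as<double>(il_conf["window"]);
    il.delay = as<double>(il_conf["delay"]);
    il.refractory = as<double>(il_conf["refractory"]);
    il.sync_fraction = as<double>(il_conf["sync_fraction"]);
    il.gsyn = as<double>(il_conf["gsyn_density"]);
    il.Esyn = as<double>(il_conf["E_syn"]);
    il.alpha = as<double>(il_conf["alpha"]);
    il.beta = as<double>(il_conf["beta"]);
    il.Tconc = as<double>(il_conf["T_conc"]);
    il.Tdur = as<double>(il_conf["T_dur"]);
    il.check_dt = as<double>(il_conf["check_dt"]);
    sense.resize(il_sense.size());
    feedback.resize(il_feedback.size());
    for (int u = 0; u < il_sense.size(); ++u) {
      IntegerVector v = il_sense[u];
      for (int j : v) sense[u].push_back(j - 1);
    }
    for (int u = 0; u < il_feedback.size(); ++u) {
      IntegerVector v = il_feedback[u];
      for (int j : v) feedback[u].push_back(j - 1);
    }
  }

  const int NS = 8 * N;
  // when the loop is off the synaptic-gate block is identically zero and is
  // excluded from the integration loops
  const int NSa = (il_conf.size() > 0) ? NS : 7 * N;
  std::vector<double> y(NS, 0.0), ynew(NS, 0.0), work(NS, 0.0);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 7; ++k) y[k * N + i] = y0(i, k);

  // Verner 6(5) pair (8 stages)
  const double c2 = 1.0 / 6, c3 = 4.0 / 15, c4 = 2.0 / 3, c5 = 5.0 / 6,
               c6 = 1.0, c7 = 1.0 / 15, c8 = 1.0;
  static const double A[8][7] = {
    {0, 0, 0, 0, 0, 0, 0},
    {1.0 / 6, 0, 0, 0, 0, 0, 0},
    {4.0 / 75, 16.0 / 75, 0, 0, 0, 0, 0},
    {5.0 / 6, -8.0 / 3, 5.0 / 2, 0, 0, 0, 0},
    {-165.0 / 64, 55.0 / 6, -425.0 / 64, 85.0 / 96, 0, 0, 0},
    {12.0 / 5, -8.0, 4015.0 / 612, -11.0 / 36, 88.0 / 255, 0, 0},
    {-8263.0 / 15000, 124.0 / 75, -643.0 / 680, -81.0 / 250,
     2484.0 / 10625, 0, 0},
    {3501.0 / 1720, -300.0 / 43, 297275.0 / 52632, -319.0 / 2322,
     24068.0 / 84065, 0, 3850.0 / 26703}
  };
  static const double B6[8] = {3.0 / 40, 0, 875.0 / 2244, 23.0 / 72,
                               264.0 / 1955, 0, 125.0 / 11592, 43.0 / 616};
  static const double B5[8] = {13.0 / 160, 0, 2375.0 / 5984, 5.0 / 16,
                               12.0 / 85, 3.0 / 44, 0, 0};
  const double CS[8] = {0, c2, c3, c4, c5, c6, c7, c8};
  std::vector<std::vector<double>> kst(8, std::vector<double>(NS, 0.0));
  double* kp[8];
  for (int q = 0; q < 8; ++q) kp[q] = kst[q].data();

  // recording
  const int n_frames = (int)std::floor(duration / dt_record + 1e-9) + 1;
  const int n_rec = record_full ? 7 * N : N;
  NumericMatrix frames(n_frames, n_rec);
  std::vector<double> frame_t(n_frames);
  int next_frame = 0;

  // spikes
  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  std::vector<double> last_spike(N, -1e18);

  // drive epochs
  int n_epoch = Iinj_epochs.nrow();
  int cur_epoch = 0;
  std::vector<double> Iinj(N), sigma(N);
  auto load_epoch = [&](int ep) {
    for (int i = 0; i < N; ++i) {
      Iinj[i] = Iinj_epochs(ep, i);
      sigma[i] = sigma_epochs(ep, i);
    }
  };
  load_epoch(0);

  // inhibitory-loop state
  std::vector<double> Tval(N, 0.0);
  std::vector<double> pulse_until(N, -1.0);
  std::vector<double> next_allowed(il.on ? (int)sense.size() : 0, 0.0);
  typedef std::pair<double, int> Ev; // (time, unit) IPSP onsets
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev>> onset_q;
  std::priority_queue<double, std::vector<double>,
                      std::greater<double>> offset_q;
  std::vector<int> il_fire_unit;
  std::vector<double> il_fire_time;
  double next_il_check = il.on ? 0.0 : 1e300;

  double t = 0.0, h = std::min(0.01, dt_max);
  long n_steps = 0, n_rejected = 0;
  const double tiny = 1e-9;

  // record frame 0
  for (int m = 0; m < n_rec; ++m) frames(0, m) = y[m];
  frame_t[0] = 0.0;
  next_frame = 1;

  while (t < duration - tiny) {
    // next hard boundary the step must not cross
    double stop = duration;
    if (next_frame < n_frames)
      stop = std::min(stop, next_frame * dt_record);
    if (cur_epoch + 1 < n_epoch)
      stop = std::min(stop, epoch_start[cur_epoch + 1]);
    if (il.on) {
      stop = std::min(stop, next_il_check);
      if (!onset_q.empty()) stop = std::min(stop, onset_q.top().first);
      if (!offset_q.empty()) stop = std::min(stop, offset_q.top());
    }
    if (stop <= t + tiny) stop = t + tiny; // guard, handled below anyway

    h = std::min(h, dt_max);
    const bool truncated = (t + h > stop);
    const double hu = truncated ? (stop - t) : h;

    // stage computations
    rhs(y, kst[0], N, nbr.data(), deg.data(), K, g_c, P, Iinj.data(),
        sigma.data(), ramp_rate * t, Tval.data(), il);
    for (int st = 1; st < 8; ++st) {
      const double* Ast = A[st];
      for (int m = 0; m < NSa; ++m) {
        double acc = Ast[0] * kp[0][m];
        for (int q = 1; q < st; ++q) acc += Ast[q] * kp[q][m];
        work[m] = y[m] + hu * acc;
      }
      rhs(work, kst[st], N, nbr.data(), deg.data(), K, g_c, P, Iinj.data(),
          sigma.data(), ramp_rate * (t + CS[st] * hu), Tval.data(), il);
    }
    double err = 0.0;
    // B6 has zero weights at stages 2 and 6, B5 at stages 7 and 8
    for (int m = 0; m < NSa; ++m) {
      const double acc6 = B6[0] * kp[0][m] + B6[2] * kp[2][m] +
                          B6[3] * kp[3][m] + B6[4] * kp[4][m] +
                          B6[6] * kp[6][m] + B6[7] * kp[7][m];
      const double acc5 = B5[0] * kp[0][m] + B5[2] * kp[2][m] +
                          B5[3] * kp[3][m] + B5[4] * kp[4][m] +
                          B5[5] * kp[5][m];
      ynew[m] = y[m] + hu * acc6;
      const double e = std::fabs(hu * (acc6 - acc5));
      if (e > err) err = e;
    }
    ++n_steps;
    double fac = (err > 0.0) ? 0.9 * std::pow(max_error / err, 1.0 / 6.0)
                             : 5.0;
    if (err > max_error) {
      ++n_rejected;
      h = hu * std::max(0.1, fac);
      if (h < 1e-10)
        Rcpp::stop("integration step size underflow at t = %.6f ms", t);
      continue;
    }

    const double t_new = t + hu;
    // spike detection on accepted step
    for (int i = 0; i < N; ++i) {
      if (y[i] <= spike_threshold && ynew[i] > spike_threshold &&
          t_new - last_spike[i] >= spike_rearm) {
        double frac = (spike_threshold - y[i]) / (ynew[i] - y[i]);
        double ts = t + frac * hu;
        last_spike[i] = ts;
        spike_cell.push_back(i + 1);
        spike_time.push_back(ts);
      }
    }
    y.swap(ynew);
    t = t_new;

    // controller update: a boundary-truncated step does not shrink the
    // natural step size
    if (!truncated) {
      h = hu * std::min(5.0, std::max(0.2, fac));
      if (h < 1e-10) h = 1e-10;
    }

    // boundary actions
    while (next_frame < n_frames &&
           t >= next_frame * dt_record - tiny) {
      for (int m = 0; m < n_rec; ++m) frames(next_frame, m) = y[m];
      frame_t[next_frame] = next_frame * dt_record;
      ++next_frame;
    }
    while (cur_epoch + 1 < n_epoch && t >= epoch_start[cur_epoch + 1] - tiny) {
      ++cur_epoch;
      load_epoch(cur_epoch);
    }
    if (il.on) {
      // transmitter pulse edges
      while (!onset_q.empty() && onset_q.top().first <= t + tiny) {
        int u = onset_q.top().second;
        double te = onset_q.top().first;
        onset_q.pop();
        for (int j : feedback[u]) {
          Tval[j] = il.Tconc;
          double off = te + il.Tdur;
          if (off > pulse_until[j]) pulse_until[j] = off;
          offset_q.push(off);
        }
      }
      while (!offset_q.empty() && offset_q.top() <= t + tiny) offset_q.pop();
      for (int j = 0; j < N; ++j)
        if (Tval[j] > 0.0 && t >= pulse_until[j] - tiny) Tval[j] = 0.0;
      // synchrony detection at the check cadence
      while (next_il_check <= t + tiny) {
        double tc = next_il_check;
        for (size_t u = 0; u < sense.size(); ++u) {
          if (tc < next_allowed[u] || sense[u].empty()) continue;
          int cnt = 0;
          for (int j : sense[u])
            if (last_spike[j] >= tc - il.window) ++cnt;
          if (cnt >= std::ceil(il.sync_fraction * sense[u].size()) &&
              cnt > 0) {
            next_allowed[u] = tc + il.refractory;
            onset_q.push(Ev(tc + il.delay, (int)u));
            il_fire_unit.push_back((int)u + 1);
            il_fire_time.push_back(tc);
          }
        }
        next_il_check += il.check_dt;
      }
    }
  }

  List spikes = List::create(_["cell"] = IntegerVector(spike_cell.begin(),
                                                       spike_cell.end()),
                             _["time"] = NumericVector(spike_time.begin(),
                                                       spike_time.end()));
  List il_log = List::create(_["unit"] = IntegerVector(il_fire_unit.begin(),
                                                       il_fire_unit.end()),
                             _["time"] = NumericVector(il_fire_time.begin(),
                                                       il_fire_time.end()));
  return List::create(_["frames"] = frames,
                      _["frame_times"] = NumericVector(frame_t.begin(),
                                                       frame_t.end()),
                      _["spikes"] = spikes,
                      _["il_log"] = il_log,
                      _["n_steps"] = (double)n_steps,
                      _["n_rejected"] = (double)n_rejected);
}
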