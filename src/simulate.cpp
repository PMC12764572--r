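// Integration cores for the burst-network simulator.
//
// Three entry points:
//   cpp_simulate_neuron  - single HR / LHR neuron, first-order Euler,
//                          constant input current
//   cpp_simulate_fixed   - single LHR neuron on the fixed-point shift-and-add
//                          datapath (bit-deterministic, int64 registers)
//   cpp_network_trial    - one trial of the layered network: per-neuron
//                          AMPA/GABA filters, delayed impulse delivery,
//                          refractory-gated spike transmission
//
// The piecewise tables use half-open [lo, hi) segments: a breakpoint value
// belongs to the higher segment.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------- piecewise-linear evaluation (float) ----------

static inline double pwl_eval(double x,
                              const std::vector<double>& br,
                              const std::vector<double>& slope,
                              const std::vector<double>& intercept) {
  // index = number of breakpoints <= x  (breakpoint goes to higher segment)
  size_t idx = std::upper_bound(br.begin(), br.end(), x) - br.begin();
  return slope[idx] * x + intercept[idx];
}

// flat-array variant for the hot network loop (tables are ~10 segments,
// a predictable linear scan beats binary search)
static inline double pwl_eval_fast(double x, const double* br, int nbr,
                                   const double* slope,
                                   const double* intercept) {
  int idx = 0;
  while (idx < nbr && x >= br[idx]) ++idx;
  return slope[idx] * x + intercept[idx];
}

static std::vector<double> as_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// ---------- HR / LHR derivatives ----------

struct HRP {
  double a, b, c, d, r, s, q, I;
};

static inline void hr_rhs(double x, double y, double z, const HRP& p,
                          double& dx, double& dy, double& dz) {
  dx = y - p.a * x * x * x + p.b * x * x - z + p.I;
  dy = p.c - p.d * x * x - y;
  dz = p.r * (p.s * (x - p.q) - z);
}

static inline void lhr_rhs(double x, double y, double z, const HRP& p,
                           const std::vector<double>& cbr,
                           const std::vector<double>& csl,
                           const std::vector<double>& cin,
                           const std::vector<double>& sbr,
                           const std::vector<double>& ssl,
                           const std::vector<double>& sin,
                           double& dx, double& dy, double& dz) {
  double x3 = pwl_eval(x, cbr, csl, cin);
  double x2 = pwl_eval(x, sbr, ssl, sin);
  dx = y - p.a * x3 + p.b * x2 - z + p.I;
  dy = p.c - p.d * x2 - y;
  dz = p.r * (p.s * (x - p.q) - z);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_neuron(int model,
                                  NumericVector params,
                                  NumericVector ic,
                                  int n_steps,
                                  double dt,
                                  NumericVector cube_br, NumericVector cube_sl,
                                  NumericVector cube_in,
                                  NumericVector sq_br, NumericVector sq_sl,
                                  NumericVector sq_in,
                                  double guard) {
  HRP p{params[0], params[1], params[2], params[3],
        params[4], params[5], params[6], params[7]};
  std::vector<double> cbr = as_vec(cube_br), csl = as_vec(cube_sl),
      cin = as_vec(cube_in), sbr = as_vec(sq_br), ssl = as_vec(sq_sl),
      sin = as_vec(sq_in);
  NumericMatrix out(n_steps + 1, 3);
  double x = ic[0], y = ic[1], z = ic[2];
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = z;
  double dx, dy, dz;
  for (int n = 0; n < n_steps; ++n) {
    if (model == 0) hr_rhs(x, y, z, p, dx, dy, dz);
    else lhr_rhs(x, y, z, p, cbr, csl, cin, sbr, ssl, sin, dx, dy, dz);
    x += dt * dx; y += dt * dy; z += dt * dz;
    if (!(std::fabs(x) < guard))
      stop("integration failure: |x| exceeded guard %.1f at step %d",
           guard, n + 1);
    out(n + 1, 0) = x; out(n + 1, 1) = y; out(n + 1, 2) = z;
  }
  return out;
}

// ---------- fixed-point shift-and-add datapath ----------

// A constant multiplier is a signed sum of powers of two: value ~ sum_i
// sign_i * 2^shift_i. Multiplying a Q-format register by it needs only
// arithmetic shifts and adds.

struct SAPlan {
  std::vector<int> sign;
  std::vector<int> shift;
};

static inline int64_t shr_arith(int64_t v, int k) {
  // arithmetic right shift == floor division by 2^k
  return v < 0 ? ~((~v) >> k) : v >> k;
}

static inline int64_t apply_plan(int64_t v, const SAPlan& pl) {
  int64_t acc = 0;
  for (size_t i = 0; i < pl.sign.size(); ++i) {
    int k = pl.shift[i];
    int64_t term = (k >= 0) ? (v * (int64_t(1) << k)) : shr_arith(v, -k);
    acc += pl.sign[i] > 0 ? term : -term;
  }
  return acc;
}

static SAPlan parse_plan(const IntegerMatrix& m) {
  SAPlan pl;
  for (int i = 0; i < m.nrow(); ++i) {
    pl.sign.push_back(m(i, 0));
    pl.shift.push_back(m(i, 1));
  }
  return pl;
}

struct FixedModel {
  int frac_bits, int_bits, dt_shift;
  int64_t sat_lim;
  SAPlan a_pl, b_pl, d_pl, r_pl, s_pl;
  int64_t c_q, q_q;
  std::vector<int64_t> cube_br, cube_in, sq_br, sq_in;
  std::vector<SAPlan> cube_sl, sq_sl;
};

static std::vector<int64_t> as_i64(const NumericVector& v) {
  std::vector<int64_t> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (int64_t) v[i];
  return out;
}

static std::vector<SAPlan> parse_plans(const List& l) {
  std::vector<SAPlan> out;
  for (int i = 0; i < l.size(); ++i)
    out.push_back(parse_plan(as<IntegerMatrix>(l[i])));
  return out;
}

static FixedModel parse_fixed(const List& fx) {
  FixedModel m;
  m.frac_bits = as<int>(fx["frac_bits"]);
  m.int_bits  = as<int>(fx["int_bits"]);
  m.dt_shift  = as<int>(fx["dt_shift"]);
  m.sat_lim   = (int64_t(1) << (m.int_bits + m.frac_bits)) - 1;
  m.a_pl = parse_plan(as<IntegerMatrix>(fx["a_plan"]));
  m.b_pl = parse_plan(as<IntegerMatrix>(fx["b_plan"]));
  m.d_pl = parse_plan(as<IntegerMatrix>(fx["d_plan"]));
  m.r_pl = parse_plan(as<IntegerMatrix>(fx["r_plan"]));
  m.s_pl = parse_plan(as<IntegerMatrix>(fx["s_plan"]));
  m.c_q = (int64_t) as<double>(fx["c_q"]);
  m.q_q = (int64_t) as<double>(fx["q_q"]);
  m.cube_br = as_i64(fx["cube_br_q"]);
  m.cube_in = as_i64(fx["cube_in_q"]);
  m.sq_br   = as_i64(fx["sq_br_q"]);
  m.sq_in   = as_i64(fx["sq_in_q"]);
  m.cube_sl = parse_plans(as<List>(fx["cube_sl_plans"]));
  m.sq_sl   = parse_plans(as<List>(fx["sq_sl_plans"]));
  return m;
}

static inline int64_t saturate(int64_t v, int64_t lim, long& n_sat) {
  if (v > lim)  { ++n_sat; return lim; }
  if (v < -lim) { ++n_sat; return -lim; }
  return v;
}

static inline int64_t pwl_fixed(int64_t x, const std::vector<int64_t>& br,
                                const std::vector<SAPlan>& sl,
                                const std::vector<int64_t>& in) {
  size_t idx = std::upper_bound(br.begin(), br.end(), x) - br.begin();
  return apply_plan(x, sl[idx]) + in[idx];
}

// One Euler step of the fixed LHR datapath. All quantities are Q(int_bits,
// frac_bits) integers; the dt multiply is an arithmetic right shift.
static inline void fixed_step(int64_t& X, int64_t& Y, int64_t& Z, int64_t Iq,
                              const FixedModel& m, long& n_sat) {
  int64_t f3 = pwl_fixed(X, m.cube_br, m.cube_sl, m.cube_in);
  int64_t f2 = pwl_fixed(X, m.sq_br, m.sq_sl, m.sq_in);
  int64_t dX = Y - apply_plan(f3, m.a_pl) + apply_plan(f2, m.b_pl) - Z + Iq;
  int64_t dY = m.c_q - apply_plan(f2, m.d_pl) - Y;
  int64_t dZ = apply_plan(apply_plan(X - m.q_q, m.s_pl) - Z, m.r_pl);
  X = saturate(X + shr_arith(dX, m.dt_shift), m.sat_lim, n_sat);
  Y = saturate(Y + shr_arith(dY, m.dt_shift), m.sat_lim, n_sat);
  Z = saturate(Z + shr_arith(dZ, m.dt_shift), m.sat_lim, n_sat);
}

// [[Rcpp::export]]
List cpp_simulate_fixed(List fx, NumericVector ic_q, double I_q, int n_steps) {
  FixedModel m = parse_fixed(fx);
  int64_t X = (int64_t) ic_q[0], Y = (int64_t) ic_q[1], Z = (int64_t) ic_q[2];
  int64_t Iq = (int64_t) I_q;
  long n_sat = 0;
  NumericMatrix out(n_steps + 1, 3);
  double sc = std::ldexp(1.0, -m.frac_bits);
  out(0, 0) = X * sc; out(0, 1) = Y * sc; out(0, 2) = Z * sc;
  for (int n = 0; n < n_steps; ++n) {
    fixed_step(X, Y, Z, Iq, m, n_sat);
    out(n + 1, 0) = X * sc; out(n + 1, 1) = Y * sc; out(n + 1, 2) = Z * sc;
  }
  return List::create(_["trace"] = out, _["n_saturations"] = n_sat);
}

// ---------- network trial ----------

// Neurons are indexed globally: [0, n2) layer 2, [n2, n2+n_out) output,
// [n2+n_out, N) critic. Only layer-2 neurons have outgoing modeled synapses
// (CSR arrays src_ptr / syn_dst / syn_w). Input ganglion cells deliver
// pre-computed spikes through their own CSR (in_ptr / in_dst / in_w).
// All impulses arrive tau_L after the presynaptic event.

// [[Rcpp::export]]
List cpp_network_trial(int n2, int n_exc, int n_out, int n_crit,
                       IntegerVector src_ptr, IntegerVector syn_dst,
                       NumericVector syn_w,
                       IntegerVector in_ptr, IntegerVector in_dst,
                       NumericVector in_w,
                       IntegerVector in_spike_step, IntegerVector in_spike_cell,
                       int n_steps, double dt,
                       NumericVector params,       // a b c d r s q (I from synapses)
                       NumericVector tau_m,        // per neuron
                       NumericVector tau_rp,       // per neuron
                       double tau_dA, double tau_rA,
                       double tau_dG, double tau_rG,
                       double tau_L,
                       double spike_threshold,
                       int model,                  // 0 HR, 1 LHR, 2 LHR fixed
                       NumericVector cube_br, NumericVector cube_sl,
                       NumericVector cube_in,
                       NumericVector sq_br, NumericVector sq_sl,
                       NumericVector sq_in,
                       List fx,                    // fixed model (model == 2)
                       NumericVector ic,
                       double guard, double drive_max,
                       double output_bias) {
  const int N = n2 + n_out + n_crit;
  HRP p{params[0], params[1], params[2], params[3],
        params[4], params[5], params[6], 0.0};
  std::vector<double> cbr = as_vec(cube_br), csl = as_vec(cube_sl),
      cin = as_vec(cube_in), sbr = as_vec(sq_br), ssl = as_vec(sq_sl),
      sin = as_vec(sq_in);

  FixedModel fm;
  std::vector<int64_t> Xq, Yq, Zq;
  long n_sat = 0;
  double fsc = 1.0;
  if (model == 2) {
    fm = parse_fixed(fx);
    fsc = std::ldexp(1.0, -fm.frac_bits);
  }

  std::vector<double> x(N, ic[0]), y(N, ic[1]), z(N, ic[2]);
  if (model == 2) {
    Xq.assign(N, (int64_t) std::llround(ic[0] / fsc));
    Yq.assign(N, (int64_t) std::llround(ic[1] / fsc));
    Zq.assign(N, (int64_t) std::llround(ic[2] / fsc));
  }
  std::vector<double> IA(N, 0.0), xA(N, 0.0), IG(N, 0.0), xG(N, 0.0);
  std::vector<double> last_spike(N, -1e9);

  const int delay_steps = (int) std::lround(tau_L / dt);
  std::vector<std::vector<int>> ring(delay_steps + 1);

  // walk pointer over input events, delivered delay_steps after emission
  int ev = 0;
  const int n_ev = in_spike_step.size();

  const double kA = dt / tau_dA, krA = dt / tau_rA;
  const double kG = dt / tau_dG, krG = dt / tau_rG;

  // flat copies for the hot loop
  std::vector<double> tm(tau_m.begin(), tau_m.end());
  std::vector<double> trp(tau_rp.begin(), tau_rp.end());
  const double a_ = p.a, b_ = p.b, c_ = p.c, d_ = p.d,
      r_ = p.r, s_ = p.s, q_ = p.q;
  const double* cbrp = cbr.data(); const int ncbr = (int) cbr.size();
  const double* cslp = csl.data(); const double* cinp = cin.data();
  const double* sbrp = sbr.data(); const int nsbr = (int) sbr.size();
  const double* sslp = ssl.data(); const double* sinp = sin.data();

  std::vector<int> sp_step;
  std::vector<int> sp_neuron;
  sp_step.reserve(1024);
  sp_neuron.reserve(1024);

  double dx, dy, dz;
  for (int n = 0; n < n_steps; ++n) {
    // 1. deliver delayed recurrent impulses
    std::vector<int>& bucket = ring[n % (delay_steps + 1)];
    for (int s : bucket) {
      bool exc = s < n_exc;
      for (int j = src_ptr[s]; j < src_ptr[s + 1]; ++j) {
        int dsti = syn_dst[j];
        if (exc) xA[dsti] += tm[dsti] * syn_w[j] / tau_rA;
        else     xG[dsti] += tm[dsti] * syn_w[j] / tau_rG;
      }
    }
    bucket.clear();

    // 2. deliver delayed input impulses (input cells are excitatory)
    while (ev < n_ev && in_spike_step[ev] + delay_steps == n) {
      int cell = in_spike_cell[ev];
      for (int j = in_ptr[cell]; j < in_ptr[cell + 1]; ++j) {
        int dsti = in_dst[j];
        xA[dsti] += tm[dsti] * in_w[j] / tau_rA;
      }
      ++ev;
    }

    // 3. synaptic filters (Euler) and neuron update
    for (int i = 0; i < N; ++i) {
      IA[i] += kA * (xA[i] - IA[i]);
      xA[i] -= krA * xA[i];
      IG[i] += kG * (xG[i] - IG[i]);
      xG[i] -= krG * xG[i];
      double Isyn = IA[i] - IG[i];
      // saturate the drive: the piecewise-linear tables only emulate the
      // cubic inside their breakpoint span, and the hardware input
      // register is bounded anyway
      if (Isyn > drive_max) Isyn = drive_max;
      else if (Isyn < -drive_max) Isyn = -drive_max;
      if (i >= n2) Isyn += output_bias;   // tonic drive of the readout layers
      double xprev = x[i];
      if (model == 2) {
        int64_t Iq = (int64_t) std::llround(Isyn / fsc);
        fixed_step(Xq[i], Yq[i], Zq[i], Iq, fm, n_sat);
        x[i] = Xq[i] * fsc;
      } else {
        double xi = x[i], yi = y[i], zi = z[i];
        double x3, x2;
        if (model == 0) { x3 = xi * xi * xi; x2 = xi * xi; }
        else {
          x3 = pwl_eval_fast(xi, cbrp, ncbr, cslp, cinp);
          x2 = pwl_eval_fast(xi, sbrp, nsbr, sslp, sinp);
        }
        double dx_ = yi - a_ * x3 + b_ * x2 - zi + Isyn;
        double dy_ = c_ - d_ * x2 - yi;
        double dz_ = r_ * (s_ * (xi - q_) - zi);
        xi += dt * dx_; y[i] = yi + dt * dy_; z[i] = zi + dt * dz_;
        x[i] = xi;
        if (!(std::fabs(xi) < guard))
          stop("integration failure: |x| exceeded guard %.1f (neuron %d, step %d)",
               guard, i + 1, n + 1);
      }

      // 4. refractory-gated spike detection on upward threshold crossing
      if (xprev < spike_threshold && x[i] >= spike_threshold) {
        double t = (n + 1) * dt;
        if (t - last_spike[i] >= trp[i]) {
          last_spike[i] = t;
          sp_step.push_back(n + 1);
          sp_neuron.push_back(i);
          if (i < n2)  // only layer-2 neurons project within the model
            ring[(n + delay_steps) % (delay_steps + 1)].push_back(i);
        }
      }
    }
  }

  return List::create(_["spike_step"] = wrap(sp_step),
                      _["spike_neuron"] = wrap(sp_neuron),
                      _["n_saturations"] = n_sat);
}
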