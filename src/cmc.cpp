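#include <Rcpp.h>
using namespace Rcpp;

// Canonical microcircuit column: 4 populations, 2 states each (voltage v, current i).
// Population order everywhere: 0 = SS, 1 = SP, 2 = II, 3 = DP.
//
// Intrinsic wiring (source, target, sign); gains g[k] >= 0 carry the magnitude,
// the sign is fixed by the canonical circuit:
//   SS->SS(-) SP->SS(-) II->SS(-) II->II(-) SS->II(+)
//   DP->II(+) SP->SP(-) SS->SP(+) II->DP(-) DP->DP(-)
static const int    W_SRC[10] = {0, 1, 2, 2, 0, 3, 1, 0, 2, 3};
static const int    W_TGT[10] = {0, 0, 0, 2, 2, 2, 1, 1, 3, 3};
static const double W_SGN[10] = {-1, -1, -1, -1, +1, +1, -1, +1, -1, -1};

// Presynaptic firing: centred sigmoid, S(0) = 0 so the zero state is a fixed point.
static inline double sig(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}

// drive(4 x R): signed, gain-weighted presynaptic input per population.
static void compute_drive(const double* v, int R,
                          const double* g, const double* r,
                          const int* ef_src, const int* ef_tgt, const double* af, int n_f,
                          const int* eb_src, const int* eb_tgt, const double* ab, int n_b,
                          const int* inp, const double* cin, int n_in,
                          double u, double* drive) {
  std::vector<double> S(4 * R);
  for (int j = 0; j < R; ++j)
    for (int p = 0; p < 4; ++p)
      S[p + 4 * j] = sig(v[p + 4 * j], r[j]);
  std::fill(drive, drive + 4 * R, 0.0);
  for (int j = 0; j < R; ++j)
    for (int k = 0; k < 10; ++k)
      drive[W_TGT[k] + 4 * j] += W_SGN[k] * g[k + 10 * j] * S[W_SRC[k] + 4 * j];
  // forward: SP of source -> SS and DP of target
  for (int e = 0; e < n_f; ++e) {
    double s = af[e] * S[1 + 4 * ef_src[e]];
    drive[0 + 4 * ef_tgt[e]] += s;
    drive[3 + 4 * ef_tgt[e]] += s;
  }
  // backward: DP of source -> SP and II of target
  for (int e = 0; e < n_b; ++e) {
    double s = ab[e] * S[3 + 4 * eb_src[e]];
    drive[1 + 4 * eb_tgt[e]] += s;
    drive[2 + 4 * eb_tgt[e]] += s;
  }
  // exogenous input onto SS of input regions
  for (int e = 0; e < n_in; ++e)
    drive[0 + 4 * inp[e]] += cin[e] * u;
}

static void deriv(const double* v, const double* i, int R,
                  const double* kappa, const double* g, const double* r,
                  const int* ef_src, const int* ef_tgt, const double* af, int n_f,
                  const int* eb_src, const int* eb_tgt, const double* ab, int n_b,
                  const int* inp, const double* cin, int n_in,
                  double u, double* dv, double* di, double* scratch) {
  compute_drive(v, R, g, r, ef_src, ef_tgt, af, n_f, eb_src, eb_tgt, ab, n_b,
                inp, cin, n_in, u, scratch);
  for (int j = 0; j < R; ++j)
    for (int p = 0; p < 4; ++p) {
      int idx = p + 4 * j;
      double k = kappa[idx];
      dv[idx] = i[idx];
      di[idx] = k * scratch[idx] - 2.0 * k * i[idx] - k * k * v[idx];
    }
}

// [[Rcpp::export]]
List cmc_deriv_cpp(NumericMatrix v, NumericMatrix i,
                   NumericMatrix kappa, NumericMatrix g, NumericVector r,
                   IntegerVector ef_src, IntegerVector ef_tgt, NumericVector af,
                   IntegerVector eb_src, IntegerVector eb_tgt, NumericVector ab,
                   IntegerVector inp, NumericVector cin, double u) {
  int R = v.ncol();
  NumericMatrix dv(4, R), di(4, R);
  std::vector<double> scratch(4 * R);
  deriv(v.begin(), i.begin(), R, kappa.begin(), g.begin(), r.begin(),
        ef_src.begin(), ef_tgt.begin(), af.begin(), ef_src.size(),
        eb_src.begin(), eb_tgt.begin(), ab.begin(), eb_src.size(),
        inp.begin(), cin.begin(), inp.size(), u, &dv[0], &di[0], scratch.data());
  return List::create(_["dv"] = dv, _["di"] = di);
}

// Fixed-step classical RK4 from the zero state; the exogenous input is a
// cumulative-Gaussian ramp amp * Phi((t - mu) / sigma).
// [[Rcpp::export]]
List cmc_integrate_cpp(NumericMatrix kappa, NumericMatrix g, NumericVector r,
                       IntegerVector ef_src, IntegerVector ef_tgt, NumericVector af,
                       IntegerVector eb_src, IntegerVector eb_tgt, NumericVector ab,
                       IntegerVector inp, NumericVector cin,
                       double amp, double mu, double sigma,
                       double t_start, double t_end, double dt) {
  int R = kappa.ncol();
  int n = (int) std::llround((t_end - t_start) / dt) + 1;
  int S = 4 * R;
  NumericMatrix vout(S, n), iout(S, n);
  NumericVector time(n);
  std::vector<double> v(S, 0.0), ii(S, 0.0), scratch(S);
  std::vector<double> k1v(S), k1i(S), k2v(S), k2i(S), k3v(S), k3i(S), k4v(S), k4i(S);
  std::vector<double> tv(S), ti(S);
  int n_f = ef_src.size(), n_b = eb_src.size(), n_in = inp.size();

  for (int step = 0; step < n; ++step) {
    double t = t_start + step * dt;
    time[step] = t;
    for (int s = 0; s < S; ++s) { vout(s, step) = v[s]; iout(s, step) = ii[s]; }
    if (step == n - 1) break;
    double u0 = amp * R::pnorm((t - mu) / sigma, 0.0, 1.0, 1, 0);
    double uh = amp * R::pnorm((t + dt / 2 - mu) / sigma, 0.0, 1.0, 1, 0);
    double u1 = amp * R::pnorm((t + dt - mu) / sigma, 0.0, 1.0, 1, 0);
    deriv(v.data(), ii.data(), R, kappa.begin(), g.begin(), r.begin(),
          ef_src.begin(), ef_tgt.begin(), af.begin(), n_f,
          eb_src.begin(), eb_tgt.begin(), ab.begin(), n_b,
          inp.begin(), cin.begin(), n_in, u0, k1v.data(), k1i.data(), scratch.data());
    for (int s = 0; s < S; ++s) { tv[s] = v[s] + dt / 2 * k1v[s]; ti[s] = ii[s] + dt / 2 * k1i[s]; }
    deriv(tv.data(), ti.data(), R, kappa.begin(), g.begin(), r.begin(),
          ef_src.begin(), ef_tgt.begin(), af.begin(), n_f,
          eb_src.begin(), eb_tgt.begin(), ab.begin(), n_b,
          inp.begin(), cin.begin(), n_in, uh, k2v.data(), k2i.data(), scratch.data());
    for (int s = 0; s < S; ++s) { tv[s] = v[s] + dt / 2 * k2v[s]; ti[s] = ii[s] + dt / 2 * k2i[s]; }
    deriv(tv.data(), ti.data(), R, kappa.begin(), g.begin(), r.begin(),
          ef_src.begin(), ef_tgt.begin(), af.begin(), n_f,
          eb_src.begin(), eb_tgt.begin(), ab.begin(), n_b,
          inp.begin(), cin.begin(), n_in, uh, k3v.data(), k3i.data(), scratch.data());
    for (int s = 0; s < S; ++s) { tv[s] = v[s] + dt * k3v[s]; ti[s] = ii[s] + dt * k3i[s]; }
    deriv(tv.data(), ti.data(), R, kappa.begin(), g.begin(), r.begin(),
          ef_src.begin(), ef_tgt.begin(), af.begin(), n_f,
          eb_src.begin(), eb_tgt.begin(), ab.begin(), n_b,
          inp.begin(), cin.begin(), n_in, u1, k4v.data(), k4i.data(), scratch.data());
    bool bad = false;
    for (int s = 0; s < S; ++s) {
      v[s]  += dt / 6 * (k1v[s] + 2 * k2v[s] + 2 * k3v[s] + k4v[s]);
      ii[s] += dt / 6 * (k1i[s] + 2 * k2i[s] + 2 * k3i[s] + k4i[s]);
      if (!std::isfinite(v[s]) || !std::isfinite(ii[s])) bad = true;
    }
    if (bad)
      return List::create(_["ok"] = false, _["bad_time"] = t + dt,
                          _["time"] = time, _["v"] = vout, _["i"] = iout);
  }
  return List::create(_["ok"] = true, _["bad_time"] = R_NilValue,
                      _["time"] = time, _["v"] = vout, _["i"] = iout);
}
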