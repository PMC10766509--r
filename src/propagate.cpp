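#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Built-in toy potentials. pot_id selects the analytic form, par its scalars.
//  1: quartic double well  U(x) = h (1 - (x/x0)^2)^2           par = (h, x0)
//  2: two-channel 2D well  U(x,y) = h (1 - (x/x0)^2)^2 + c y^2
//                                   + A exp(-(x/wx)^2 - (y/wy)^2)
//                          par = (h, x0, c, A, wx, wy)
static inline double pot_energy(int pot_id, const double* par, const double* x) {
  if (pot_id == 1) {
    double u = 1.0 - (x[0] / par[1]) * (x[0] / par[1]);
    return par[0] * u * u;
  }
  double u = 1.0 - (x[0] / par[1]) * (x[0] / par[1]);
  double g = std::exp(-(x[0] / par[4]) * (x[0] / par[4]) -
                       (x[1] / par[5]) * (x[1] / par[5]));
  return par[0] * u * u + par[2] * x[1] * x[1] + par[3] * g;
}

static inline void pot_grad(int pot_id, const double* par, const double* x,
                            double* g) {
  if (pot_id == 1) {
    double u = 1.0 - (x[0] / par[1]) * (x[0] / par[1]);
    g[0] = -4.0 * par[0] * x[0] * u / (par[1] * par[1]);
    return;
  }
  double u = 1.0 - (x[0] / par[1]) * (x[0] / par[1]);
  double e = std::exp(-(x[0] / par[4]) * (x[0] / par[4]) -
                       (x[1] / par[5]) * (x[1] / par[5]));
  g[0] = -4.0 * par[0] * x[0] * u / (par[1] * par[1]) -
         2.0 * par[3] * x[0] * e / (par[4] * par[4]);
  g[1] = 2.0 * par[2] * x[1] - 2.0 * par[3] * x[1] * e / (par[5] * par[5]);
}

// [[Rcpp::export]]
double cpp_potential(int pot_id, NumericVector par, NumericVector x) {
  return pot_energy(pot_id, par.begin(), x.begin());
}

// [[Rcpp::export]]
NumericVector cpp_potential_grad(int pot_id, NumericVector par,
                                 NumericVector x) {
  NumericVector g(x.size());
  pot_grad(pot_id, par.begin(), x.begin(), g.begin());
  return g;
}

// Axis-aligned box states: point is in state s iff lo(s,j) <= x_j <= hi(s,j)
// for every dimension j. Returns 1-based state index or 0.
static inline int which_state(const double* x, int dim,
                              const NumericMatrix& lo,
                              const NumericMatrix& hi) {
  int ns = lo.nrow();
  for (int s = 0; s < ns; ++s) {
    bool in = true;
    for (int j = 0; j < dim; ++j) {
      if (x[j] < lo(s, j) || x[j] > hi(s, j)) { in = false; break; }
    }
    if (in) return s + 1;
  }
  return 0;
}

// Langevin propagation until first entry into a box state (or max_steps).
// kind 0 = overdamped Euler-Maruyama: dx = -grad U/(m*friction) dt + sqrt(2 kT dt/(m*friction)) xi
// kind 1 = underdamped velocity Verlet with per-step velocity randomization
//          (half-kick, drift, half-kick, then Ornstein-Uhlenbeck velocity mix
//           v <- a v + sqrt((1-a^2) kT/m) xi with a = exp(-friction dt)).
// With zero states (lo has 0 rows) this runs exactly max_steps and returns
// the frames: the chunk mode used for model-defined (softened) states.
// record = 0 stores only the first and last frame (committor estimation).
// Uses R's RNG: seeding via set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
List cpp_propagate(int pot_id, NumericVector par, int kind,
                   NumericVector x_init, NumericVector v_init,
                   NumericVector mass, double dt, double friction, double kT,
                   int max_steps, int stride,
                   NumericMatrix state_lo, NumericMatrix state_hi,
                   int record) {
  int dim = x_init.size();
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> v(dim, 0.0);
  if (kind == 1) {
    for (int j = 0; j < dim; ++j) v[j] = v_init[j];
  }
  std::vector<double> grad(dim), frames, vframes;
  std::vector<double> sq2Ddt(dim), a_mix(dim), sig_v(dim);
  for (int j = 0; j < dim; ++j) {
    sq2Ddt[j] = std::sqrt(2.0 * kT * dt / (mass[j] * friction));
  }
  double a = std::exp(-friction * dt);
  for (int j = 0; j < dim; ++j) {
    a_mix[j] = a;
    sig_v[j] = std::sqrt((1.0 - a * a) * kT / mass[j]);
  }
  bool has_states = state_lo.nrow() > 0;
  int state = has_states ? which_state(x.data(), dim, state_lo, state_hi) : 0;

  auto push_frame = [&](void) {
    for (int j = 0; j < dim; ++j) frames.push_back(x[j]);
    if (kind == 1) for (int j = 0; j < dim; ++j) vframes.push_back(v[j]);
  };
  push_frame();
  long n_steps = 0;
  if (!(has_states && state > 0)) {
    RNGScope scope;
    for (long step = 1; step <= max_steps; ++step) {
      if (kind == 0) {
        pot_grad(pot_id, par.begin(), x.data(), grad.data());
        for (int j = 0; j < dim; ++j) {
          x[j] += -grad[j] * dt / (mass[j] * friction) +
                  sq2Ddt[j] * norm_rand();
        }
      } else {
        pot_grad(pot_id, par.begin(), x.data(), grad.data());
        for (int j = 0; j < dim; ++j) v[j] += -0.5 * dt * grad[j] / mass[j];
        for (int j = 0; j < dim; ++j) x[j] += dt * v[j];
        pot_grad(pot_id, par.begin(), x.data(), grad.data());
        for (int j = 0; j < dim; ++j) {
          v[j] += -0.5 * dt * grad[j] / mass[j];
          v[j] = a_mix[j] * v[j] + sig_v[j] * norm_rand();
        }
      }
      n_steps = step;
      state = has_states ? which_state(x.data(), dim, state_lo, state_hi) : 0;
      bool terminal = has_states && state > 0;
      if (record == 1 && (terminal || step % stride == 0)) push_frame();
      if (terminal) break;
      if (step % 100000 == 0) Rcpp::checkUserInterrupt();
    }
    if (record == 0) push_frame();
  }
  int nf = (int)(frames.size() / dim);
  NumericMatrix fm(nf, dim);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < dim; ++j) fm(i, j) = frames[(size_t)i * dim + j];
  List out = List::create(_["frames"] = fm, _["state"] = state,
                          _["n_steps"] = (double)n_steps);
  if (kind == 1) {
    NumericMatrix vm(nf, dim);
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < dim; ++j) vm(i, j) = vframes[(size_t)i * dim + j];
    out["velocities"] = vm;
  }
  return out;
}
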