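// Mass-spring skeleton integrator: semi-implicit Euler with per-edge
// distance-constraint relaxation, pinned base node, shape-memory restoring
// force toward the rest pose, sinusoidal horizontal wave forcing + drag.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_skeleton(NumericMatrix nodes, IntegerMatrix edges,
                           NumericVector rest_length, NumericVector mass,
                           double amplitude, double period,
                           double dir_x, double dir_y, double drag,
                           double duration, double dt, double stiffness,
                           int relax_iters, int save_every,
                           bool use_constant_force, double constant_force) {
  int n = nodes.nrow(), ne = edges.nrow();
  std::vector<double> x(3 * n), v(3 * n, 0.0), rest(3 * n), xp(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) rest[3 * i + k] = x[3 * i + k] = nodes(i, k);
  int nsteps = std::max(1, (int)std::ceil(duration / dt));
  if (save_every < 1) save_every = std::max(1, nsteps / 400);
  std::vector<double> times, strains;
  List frames;
  for (int s = 1; s <= nsteps; ++s) {
    double t = s * dt;
    double famp = use_constant_force ? constant_force
      : amplitude * std::sin(2.0 * M_PI * t / period);
    double fx = famp * dir_x, fy = famp * dir_y;
    for (int i = 1; i < n; ++i) {   // node 0 pinned
      double ax = (fx - stiffness * (x[3*i] - rest[3*i]) - drag * v[3*i]) / mass[i];
      double ay = (fy - stiffness * (x[3*i+1] - rest[3*i+1]) - drag * v[3*i+1]) / mass[i];
      double az = (-stiffness * (x[3*i+2] - rest[3*i+2]) - drag * v[3*i+2]) / mass[i];
      v[3*i] += dt * ax; v[3*i+1] += dt * ay; v[3*i+2] += dt * az;
    }
    xp = x;
    for (int i = 1; i < n; ++i)
      for (int k = 0; k < 3; ++k) x[3*i+k] += dt * v[3*i+k];
    for (int it = 0; it < relax_iters; ++it) {
      for (int e = 0; e < ne; ++e) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        double dx0 = x[3*b] - x[3*a], dy0 = x[3*b+1] - x[3*a+1],
               dz0 = x[3*b+2] - x[3*a+2];
        double len = std::sqrt(dx0*dx0 + dy0*dy0 + dz0*dz0);
        if (len < 1e-12) continue;
        double corr = (len - rest_length[e]) / len / 2.0;
        double sx = dx0 * corr, sy = dy0 * corr, sz = dz0 * corr;
        if (a != 0) { x[3*a] += sx; x[3*a+1] += sy; x[3*a+2] += sz; }
        if (b != 0) { x[3*b] -= sx; x[3*b+1] -= sy; x[3*b+2] -= sz; }
        if (a == 0) { x[3*b] -= sx; x[3*b+1] -= sy; x[3*b+2] -= sz; }
        if (b == 0) { x[3*a] += sx; x[3*a+1] += sy; x[3*a+2] += sz; }
      }
    }
    bool bad = false;
    for (int i = 1; i < n && !bad; ++i)
      for (int k = 0; k < 3; ++k)
        if (!std::isfinite(x[3*i+k])) { bad = true; break; }
    if (bad) stop("dynamics diverged at step %d (t = %g s)", s, t);
    for (int i = 1; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i+k] = (x[3*i+k] - xp[3*i+k]) / dt;
    if (s % save_every == 0 || s == nsteps) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) fr(i, k) = x[3*i+k];
      double mx = 0;
      for (int e = 0; e < ne; ++e) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        double dx0 = x[3*b] - x[3*a], dy0 = x[3*b+1] - x[3*a+1],
               dz0 = x[3*b+2] - x[3*a+2];
        double len = std::sqrt(dx0*dx0 + dy0*dy0 + dz0*dz0);
        mx = std::max(mx, std::fabs(len - rest_length[e]) /
                          std::max(rest_length[e], 1e-12));
      }
      times.push_back(t);
      strains.push_back(mx);
      frames.push_back(fr);
    }
  }
  return List::create(_["times"] = wrap(times), _["frames"] = frames,
                      _["max_strain"] = wrap(strains));
}
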