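// Periodic-scene ray tracing kernel for the canopy radiosity solver.
//
// The canopy geometry lives on a horizontally periodic tile: a ray leaving
// the tile re-enters on the opposite side (implemented by traversing an
// unwrapped 2D grid whose cells map back to the base tile with a shift).
// Facets are triangles with two faces (slot 2*f = +normal side, 2*f+1 =
// -normal side). Three entry points:
//   cpp_trace_direct  - per-facet occlusion-resolved weights for each
//                       zenith bin of the boundary radiance
//   cpp_gather_rays   - fixed, seeded cosine-sampled gather rays per face
//                       (hit slot + in-canopy path length)
//   cpp_jacobi_solve  - iterative gathering (Jacobi sweeps) of the
//                       Lambertian reflect/transmit exchange until the
//                       total absorbed power stabilises
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3&a,const Vec3&b){return {a.x-b.x,a.y-b.y,a.z-b.z};}
static inline Vec3 cross(const Vec3&a,const Vec3&b){
  return {a.y*b.z-a.z*b.y, a.z*b.x-a.x*b.z, a.x*b.y-a.y*b.x};}
static inline double dot(const Vec3&a,const Vec3&b){return a.x*b.x+a.y*b.y+a.z*b.z;}

// splitmix64: deterministic per-stream RNG
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double uni() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Tri {
  Vec3 a, e1, e2;   // vertex a, edges b-a, c-a
};

struct CellEntry { int tri; float bx, by, zmin, zmax; };

struct Grid {
  double tx, ty;          // tile dims
  int ncx, ncy;
  double cw, ch;          // cell size
  double ztop;
  std::vector<Tri> tris;
  std::vector<std::vector<CellEntry>> cells;

  void build(const NumericMatrix& V, const IntegerMatrix& F,
             double tilex, double tiley) {
    tx = tilex; ty = tiley;
    int nf = F.nrow();
    int nc = (int)std::ceil(std::sqrt((double)std::max(nf, 16) / 2.0));
    ncx = std::min(std::max(nc, 8), 64);
    ncy = ncx;
    cw = tx / ncx; ch = ty / ncy;
    tris.resize(nf);
    cells.assign((size_t)ncx * ncy, {});
    ztop = 0.0;
    for (int f = 0; f < nf; ++f) {
      Vec3 a{V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
      Vec3 b{V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
      Vec3 c{V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
      tris[f] = {a, sub(b,a), sub(c,a)};
      ztop = std::max(ztop, std::max(a.z, std::max(b.z, c.z)));
      double x0 = std::min(a.x, std::min(b.x, c.x)) - 1e-9;
      double x1 = std::max(a.x, std::max(b.x, c.x)) + 1e-9;
      double y0 = std::min(a.y, std::min(b.y, c.y)) - 1e-9;
      double y1 = std::max(a.y, std::max(b.y, c.y)) + 1e-9;
      int ix0 = (int)std::floor(x0 / cw), ix1 = (int)std::floor(x1 / cw);
      int iy0 = (int)std::floor(y0 / ch), iy1 = (int)std::floor(y1 / ch);
      for (int ix = ix0; ix <= ix1; ++ix) {
        int tX = (int)std::floor((double)ix / ncx);
        int iw = ix - tX * ncx;
        for (int iy = iy0; iy <= iy1; ++iy) {
          int tY = (int)std::floor((double)iy / ncy);
          int jw = iy - tY * ncy;
          cells[(size_t)iw * ncy + jw].push_back(
            {f, (float)(-tX * tx), (float)(-tY * ty),
             (float)(std::min(a.z, std::min(b.z, c.z)) - 1e-7),
             (float)(std::max(a.z, std::max(b.z, c.z)) + 1e-7)});
        }
      }
    }
  }

  // Moller-Trumbore against triangle `t` shifted by (sx, sy)
  static bool hit_tri(const Tri& t, double sx, double sy,
                      const Vec3& o, const Vec3& d,
                      double tmax, double& thit, double& sgn) {
    Vec3 a{t.a.x + sx, t.a.y + sy, t.a.z};
    Vec3 p = cross(d, t.e2);
    double det = dot(t.e1, p);
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    Vec3 tv = sub(o, a);
    double u = dot(tv, p) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) return false;
    Vec3 q = cross(tv, t.e1);
    double v = dot(d, q) * inv;
    if (v < -1e-9 || u + v > 1.0 + 1e-9) return false;
    double tt = dot(t.e2, q) * inv;
    if (tt < 1e-7 || tt > tmax) return false;
    thit = tt;
    sgn = det;   // sign of dot(normal, d): >0 means d along +normal
    return true;
  }

  // nearest hit along ray (any_hit = false) or first found occluder
  // (any_hit = true, for shadow rays); returns triangle index or -1
  // (escape). `skip` is a facet id excluded (the origin facet).
  int trace(const Vec3& o, const Vec3& d, int skip,
            double& thit, double& sgn_out, bool any_hit = false) const {
    double tmax;
    if (d.z > 1e-9)       tmax = (ztop + 1e-6 - o.z) / d.z;
    else if (d.z < -1e-9) tmax = (-1e-6 - o.z) / d.z;
    else                  tmax = 64.0 * std::max(tx, ty);
    if (tmax <= 0) return -1;

    double best = tmax;
    int bestTri = -1;
    double bestSgn = 0;

    // 2D DDA over the unwrapped grid
    double ox = o.x, oy = o.y;
    int ix = (int)std::floor(ox / cw);
    int iy = (int)std::floor(oy / ch);
    double dx = d.x, dy = d.y;
    int stepx = dx > 0 ? 1 : -1, stepy = dy > 0 ? 1 : -1;
    double tdx = (std::fabs(dx) > 1e-14) ? cw / std::fabs(dx) : 1e30;
    double tdy = (std::fabs(dy) > 1e-14) ? ch / std::fabs(dy) : 1e30;
    double nextx = (std::fabs(dx) > 1e-14)
      ? (((dx > 0 ? (ix + 1) * cw : ix * cw) - ox) / dx) : 1e30;
    double nexty = (std::fabs(dy) > 1e-14)
      ? (((dy > 0 ? (iy + 1) * ch : iy * ch) - oy) / dy) : 1e30;

    double tcur = 0.0;
    for (int guard = 0; guard < 100000; ++guard) {
      // wrapped cell + tile shift
      int tX = (int)std::floor((double)ix / ncx);
      int tY = (int)std::floor((double)iy / ncy);
      int iw = ix - tX * ncx, jw = iy - tY * ncy;
      const std::vector<CellEntry>& ce = cells[(size_t)iw * ncy + jw];
      double cell_end = std::min(std::min(nextx, nexty), tmax);
      // z-extent of the ray inside this cell, for cheap rejection
      double za = o.z + d.z * tcur, zb = o.z + d.z * cell_end;
      float zlo = (float)std::min(za, zb), zhi = (float)std::max(za, zb);
      for (const CellEntry& e : ce) {
        if (e.tri == skip) continue;
        if (e.zmax < zlo || e.zmin > zhi) continue;
        double th, sg;
        if (hit_tri(tris[e.tri], e.bx + tX * tx, e.by + tY * ty,
                    o, d, best, th, sg)) {
          if (th >= tcur - 1e-9 && th <= cell_end + 1e-9 && th < best) {
            best = th; bestTri = e.tri; bestSgn = sg;
            if (any_hit) { thit = best; sgn_out = bestSgn; return bestTri; }
          }
        }
      }
      if (bestTri >= 0 && best <= cell_end + 1e-9) break;
      if (cell_end >= tmax) break;
      if (nextx < nexty) { tcur = nextx; ix += stepx; nextx += tdx; }
      else               { tcur = nexty; iy += stepy; nexty += tdy; }
    }
    if (bestTri >= 0) { thit = best; sgn_out = bestSgn; return bestTri; }
    thit = tmax;
    return -1;
  }
};

static void facet_frames(const NumericMatrix& V, const IntegerMatrix& F,
                         std::vector<Vec3>& cent, std::vector<Vec3>& nrm) {
  int nf = F.nrow();
  cent.resize(nf); nrm.resize(nf);
  for (int f = 0; f < nf; ++f) {
    Vec3 a{V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
    Vec3 b{V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
    Vec3 c{V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
    cent[f] = {(a.x+b.x+c.x)/3.0, (a.y+b.y+c.y)/3.0, (a.z+b.z+c.z)/3.0};
    Vec3 n = cross(sub(b,a), sub(c,a));
    double L = std::sqrt(dot(n,n));
    if (L < 1e-18) L = 1.0;
    nrm[f] = {n.x/L, n.y/L, n.z/L};
  }
}

static void ortho_frame(const Vec3& n, Vec3& t1, Vec3& t2) {
  Vec3 ref = (std::fabs(n.z) < 0.9) ? Vec3{0,0,1} : Vec3{1,0,0};
  t1 = cross(ref, n);
  double L = std::sqrt(dot(t1,t1));
  t1 = {t1.x/L, t1.y/L, t1.z/L};
  t2 = cross(n, t1);
}

} // namespace

// [[Rcpp::export]]
List cpp_trace_direct(NumericMatrix V, IntegerMatrix F,
                      double tile_x, double tile_y,
                      NumericVector cos_lo, NumericVector cos_hi,
                      int n_az, int seed, double ztop_pad) {
  Grid g;
  g.build(V, F, tile_x, tile_y);
  g.ztop += ztop_pad;
  int nf = F.nrow(), nb = cos_lo.size();
  std::vector<Vec3> cent, nrm;
  facet_frames(V, F, cent, nrm);
  NumericMatrix Wup(nf, nb), Wdn(nf, nb);
  NumericMatrix Lup(nf, nb), Ldn(nf, nb);  // mean escape path length to top
  for (int f = 0; f < nf; ++f) {
    const Vec3& n = nrm[f];
    for (int b = 0; b < nb; ++b) {
      Rng rng(((uint64_t)(uint32_t)seed << 32) ^ ((uint64_t)f * 2654435761ULL + b));
      double wup = 0, wdn = 0, lup = 0, ldn = 0;
      double u_prev = 0.5;
      for (int j = 0; j < n_az; ++j) {
        // antithetic pairs in the zenith coordinate: consecutive samples
        // use u and 1-u, so the mean cosine over a pair is exact and a
        // horizontal unoccluded facet receives exactly its cosine-weighted
        // solid angle
        double u;
        if (j % 2 == 0) { u = rng.uni(); u_prev = u; } else { u = 1.0 - u_prev; }
        double mu = cos_hi[b] + (cos_lo[b] - cos_hi[b]) * u;
        double st = std::sqrt(std::max(0.0, 1.0 - mu * mu));
        double phi = 2.0 * M_PI * (j + rng.uni()) / n_az;
        Vec3 d{st * std::cos(phi), st * std::sin(phi), mu};  // upward
        double cosf = dot(n, d);
        if (std::fabs(cosf) < 1e-12) continue;
        // offset origin toward the lit side
        double off = cosf > 0 ? 1e-7 : -1e-7;
        Vec3 o{cent[f].x + n.x * off, cent[f].y + n.y * off,
               cent[f].z + n.z * off};
        double th, sg;
        int hit = g.trace(o, d, f, th, sg, /*any_hit=*/true);
        if (hit < 0) {
          double plen = (d.z > 1e-9) ? (g.ztop - cent[f].z) / d.z : th;
          if (cosf > 0) { wup += cosf; lup += plen; }
          else          { wdn -= cosf; ldn += plen; }
        }
      }
      Wup(f, b) = wup / n_az;  Wdn(f, b) = wdn / n_az;
      Lup(f, b) = lup / n_az;  Ldn(f, b) = ldn / n_az;
    }
  }
  return List::create(_["w_up"] = Wup, _["w_dn"] = Wdn,
                      _["len_up"] = Lup, _["len_dn"] = Ldn,
                      _["ztop"] = g.ztop);
}

// [[Rcpp::export]]
List cpp_gather_rays(NumericMatrix V, IntegerMatrix F,
                     double tile_x, double tile_y,
                     int n_rays, int seed, double ztop_pad) {
  Grid g;
  g.build(V, F, tile_x, tile_y);
  g.ztop += ztop_pad;
  int nf = F.nrow();
  std::vector<Vec3> cent, nrm;
  facet_frames(V, F, cent, nrm);
  int ns = 2 * nf;
  IntegerMatrix hits(ns, n_rays);   // 1-based slot hit; 0 = escaped
  NumericMatrix lens(ns, n_rays);
  for (int f = 0; f < nf; ++f) {
    Vec3 t1, t2;
    ortho_frame(nrm[f], t1, t2);
    for (int side = 0; side < 2; ++side) {
      int slot = 2 * f + side;
      double sgnn = side == 0 ? 1.0 : -1.0;
      Vec3 n{nrm[f].x * sgnn, nrm[f].y * sgnn, nrm[f].z * sgnn};
      Rng rng(((uint64_t)(uint32_t)seed << 32) ^
              ((uint64_t)slot * 0x9e3779b9ULL + 12345ULL));
      Vec3 o{cent[f].x + n.x * 1e-7, cent[f].y + n.y * 1e-7,
             cent[f].z + n.z * 1e-7};
      for (int k = 0; k < n_rays; ++k) {
        double u1 = rng.uni();
        double r = std::sqrt(u1);
        double phi = 2.0 * M_PI * (k + rng.uni()) / n_rays;  // stratified
        double zc = std::sqrt(std::max(0.0, 1.0 - u1));
        Vec3 d{r * std::cos(phi) * t1.x + r * std::sin(phi) * t2.x + zc * n.x,
               r * std::cos(phi) * t1.y + r * std::sin(phi) * t2.y + zc * n.y,
               r * std::cos(phi) * t1.z + r * std::sin(phi) * t2.z + zc * n.z};
        double th, sg;
        int hit = g.trace(o, d, f, th, sg);
        if (hit < 0) {
          hits(slot, k) = 0;
          lens(slot, k) = (d.z > 1e-9) ? (g.ztop - cent[f].z) / d.z
                                       : std::min(th, 4.0);
        } else {
          // struck face: the one facing the incoming ray (normal . d < 0);
          // Moller-Trumbore det = -d . n, so det > 0 means the +n face
          int hside = (sg > 0) ? 0 : 1;
          hits(slot, k) = 2 * hit + hside + 1;
          lens(slot, k) = th;
        }
      }
    }
  }
  return List::create(_["hits"] = hits, _["lens"] = lens, _["ztop"] = g.ztop);
}

// [[Rcpp::export]]
List cpp_jacobi_solve(IntegerMatrix hits, NumericMatrix lens,
                      NumericMatrix Edir, NumericMatrix rho,
                      NumericMatrix tau, NumericVector a_band,
                      NumericVector slot_area, double tol, int max_iters) {
  int ns = Edir.nrow(), nbands = Edir.ncol(), M = hits.ncol();
  // precompute per-ray per-band in-canopy water attenuation (float buffer)
  bool any_a = false;
  for (int b = 0; b < nbands; ++b) if (a_band[b] > 0) any_a = true;
  std::vector<float> att;
  if (any_a) {
    att.resize((size_t)ns * M * nbands);
    for (int s = 0; s < ns; ++s)
      for (int k = 0; k < M; ++k) {
        double L = lens(s, k);
        for (int b = 0; b < nbands; ++b)
          att[((size_t)s * M + k) * nbands + b] = (float)std::exp(-a_band[b] * L);
      }
  }
  NumericMatrix E(ns, nbands), B(ns, nbands), Enew(ns, nbands);
  for (int s = 0; s < ns; ++s)
    for (int b = 0; b < nbands; ++b) E(s, b) = Edir(s, b);
  double pabs_prev = -1, resid = 1;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iters; ++it) {
    // exitant radiosity: reflect same-face incident, transmit opposite-face
    for (int f = 0; f < ns / 2; ++f) {
      int s0 = 2 * f, s1 = 2 * f + 1;
      for (int b = 0; b < nbands; ++b) {
        B(s0, b) = rho(s0, b) * E(s0, b) + tau(s0, b) * E(s1, b);
        B(s1, b) = rho(s1, b) * E(s1, b) + tau(s1, b) * E(s0, b);
      }
    }
    // gather
    for (int s = 0; s < ns; ++s) {
      std::vector<double> acc(nbands, 0.0);
      for (int k = 0; k < M; ++k) {
        int h = hits(s, k);
        if (h == 0) continue;
        const double* Bh = &B(h - 1, 0);  // column-major! use row access below
        if (any_a) {
          const float* w = &att[((size_t)s * M + k) * nbands];
          for (int b = 0; b < nbands; ++b) acc[b] += B(h - 1, b) * w[b];
        } else {
          for (int b = 0; b < nbands; ++b) acc[b] += B(h - 1, b);
        }
        (void)Bh;
      }
      for (int b = 0; b < nbands; ++b)
        Enew(s, b) = Edir(s, b) + acc[b] / M;
    }
    double pabs = 0;
    for (int s = 0; s < ns; ++s)
      for (int b = 0; b < nbands; ++b)
        pabs += slot_area[s] * (1.0 - rho(s, b) - tau(s, b)) * Enew(s, b);
    std::swap(E, Enew);
    resid = (pabs_prev <= 0) ? 1.0
      : std::fabs(pabs - pabs_prev) / std::max(pabs, 1e-300);
    pabs_prev = pabs;
    if (it > 1 && resid < tol) { converged = true; break; }
  }
  // final radiosity consistent with returned E
  for (int f = 0; f < ns / 2; ++f) {
    int s0 = 2 * f, s1 = 2 * f + 1;
    for (int b = 0; b < nbands; ++b) {
      B(s0, b) = rho(s0, b) * E(s0, b) + tau(s0, b) * E(s1, b);
      B(s1, b) = rho(s1, b) * E(s1, b) + tau(s1, b) * E(s0, b);
    }
  }
  return List::create(_["E"] = E, _["B"] = B, _["iterations"] = it,
                      _["residual"] = resid, _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_trace_rays(NumericMatrix V, IntegerMatrix F,
                    double tile_x, double tile_y,
                    NumericMatrix origins, NumericMatrix dirs,
                    IntegerVector skip) {
  Grid g;
  g.build(V, F, tile_x, tile_y);
  int n = origins.nrow();
  IntegerVector hit(n);
  NumericVector tt(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o{origins(i,0), origins(i,1), origins(i,2)};
    Vec3 d{dirs(i,0), dirs(i,1), dirs(i,2)};
    double th, sg;
    int h = g.trace(o, d, skip[i] - 1, th, sg);
    hit[i] = h + 1;   // 0 = escape
    tt[i] = th;
  }
  return List::create(_["hit"] = hit, _["t"] = tt);
}
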