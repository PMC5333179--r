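// Monte Carlo core: woodcock (delta) tracking in labeled voxel volumes,
// Henyey-Greenstein phase sampling, ratio-tracking transmittance, and the
// fluorescence path tracer (camera-side walk at the emission wavelength,
// single inelastic vertex with next-event light sampling).
//
// All geometry here is in mm; attenuation coefficients in 1/mm; spectral
// quantities indexed by 0-based bin on the package wavelength grid.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: a splitmix64-seeded xorshift128+ stream per
// (seed, pixel, sample) triple, so results are independent of scheduling.

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG {
  uint64_t s0, s1;
  RNG(uint64_t seed, uint64_t a = 0, uint64_t b = 0) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + 0x853C49E6748FEA9BULL;
    x ^= a * 0xC2B2AE3D27D4EB4FULL + 0x165667B19E3779F9ULL;
    x ^= b + 0x27D4EB2F165667C5ULL;
    s0 = splitmix64_next(x);
    s1 = splitmix64_next(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, 1)
  inline double uni() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------------------

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(Vec3 a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

static inline Vec3 as_vec3(const NumericVector &v) { return {v[0], v[1], v[2]}; }

// ---------------------------------------------------------------------------

struct Pack {
  int nx, ny, nz, nb, K;
  Vec3 origin;
  double spacing;
  const int *labels;            // 0 = vacuum, 1..K material index
  const double *st, *ss, *ma, *maf, *pm;  // nb x K, column-major
  const double *g, *phi;        // K
  const double *maj;            // nb
  // camera
  Vec3 cpos, cright, cup, cfwd;
  double tanhalf;
  int W, H;
  // light (rectangle, one-sided diffuse)
  Vec3 lcorner, le1, le2, lnormal;
  double larea;
  const double *Le;             // nb
  std::vector<int> le_bins;     // bins with Le > 0
  // spectral sampling distribution over bins
  const double *spdf, *scdf;    // nb (cdf normalized to 1)
  int max_bounces, rr_depth;
  double rr_floor;
  int nee_mode;

  // keep SEXPs alive
  IntegerVector labels_;
  NumericMatrix st_, ss_, ma_, maf_, pm_;
  NumericVector g_, phi_, maj_, Le_, spdf_, scdf_;

  explicit Pack(List p) {
    IntegerVector dims = p["dims"];
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    origin = as_vec3(p["origin"]);
    spacing = as<double>(p["spacing"]);
    labels_ = p["labels"]; labels = INTEGER(labels_);
    nb = as<int>(p["nb"]); K = as<int>(p["K"]);
    st_ = as<NumericMatrix>(p["st"]); st = REAL(st_);
    ss_ = as<NumericMatrix>(p["ss"]); ss = REAL(ss_);
    ma_ = as<NumericMatrix>(p["ma"]); ma = REAL(ma_);
    maf_ = as<NumericMatrix>(p["maf"]); maf = REAL(maf_);
    pm_ = as<NumericMatrix>(p["pm"]); pm = REAL(pm_);
    g_ = p["g"]; g = REAL(g_);
    phi_ = p["phi"]; phi = REAL(phi_);
    maj_ = p["maj"]; maj = REAL(maj_);
    List cam = p["cam"];
    cpos = as_vec3(cam["pos"]); cright = as_vec3(cam["right"]);
    cup = as_vec3(cam["up"]); cfwd = as_vec3(cam["fwd"]);
    tanhalf = as<double>(cam["tanhalf"]);
    W = as<int>(cam["width"]); H = as<int>(cam["height"]);
    List light = p["light"];
    lcorner = as_vec3(light["corner"]); le1 = as_vec3(light["e1"]);
    le2 = as_vec3(light["e2"]); lnormal = as_vec3(light["normal"]);
    larea = as<double>(light["area"]);
    Le_ = light["Le"]; Le = REAL(Le_);
    for (int b = 0; b < nb; ++b) if (Le[b] > 0) le_bins.push_back(b);
    spdf_ = p["spdf"]; spdf = REAL(spdf_);
    scdf_ = p["scdf"]; scdf = REAL(scdf_);
    max_bounces = as<int>(p["max_bounces"]);
    rr_depth = as<int>(p["rr_depth"]);
    rr_floor = as<double>(p["rr_floor"]);
    nee_mode = as<int>(p["nee_mode"]);  // 0 = collision NEE, 1 = event
  }

  inline int label_at(Vec3 pnt) const {
    int i = (int)std::floor((pnt.x - origin.x) / spacing);
    int j = (int)std::floor((pnt.y - origin.y) / spacing);
    int k = (int)std::floor((pnt.z - origin.z) / spacing);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return labels[i + (size_t)nx * (j + (size_t)ny * k)];
  }

  // overlap of a ray with the grid bounding box; returns false if none
  inline bool box_overlap(Vec3 o, Vec3 d, double &t0, double &t1) const {
    double lo[3] = {origin.x, origin.y, origin.z};
    double hi[3] = {origin.x + nx * spacing, origin.y + ny * spacing,
                    origin.z + nz * spacing};
    double oo[3] = {o.x, o.y, o.z}, dd[3] = {d.x, d.y, d.z};
    t0 = 0.0; t1 = 1e300;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dd[a]) < 1e-15) {
        if (oo[a] < lo[a] || oo[a] > hi[a]) return false;
      } else {
        double ta = (lo[a] - oo[a]) / dd[a];
        double tb = (hi[a] - oo[a]) / dd[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    return t1 > t0;
  }
};

// ---------------------------------------------------------------------------
// Henyey-Greenstein phase function

static inline double hg_eval(double g, double cost) {
  const double inv4pi = 0.07957747154594767;
  if (std::fabs(g) < 1e-9) return inv4pi;
  double denom = 1.0 + g * g - 2.0 * g * cost;
  if (denom < 1e-12) denom = 1e-12;
  return inv4pi * (1.0 - g * g) / (denom * std::sqrt(denom));
}

static inline double hg_sample_cost(double g, double u) {
  if (std::fabs(g) < 1e-9) return 1.0 - 2.0 * u;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - s * s) / (2.0 * g);
  if (c < -1.0) c = -1.0;
  if (c > 1.0) c = 1.0;
  return c;
}

static inline void onb(Vec3 w, Vec3 &u, Vec3 &v) {
  if (std::fabs(w.x) > 0.9) u = normalize(cross(w, Vec3{0, 1, 0}));
  else u = normalize(cross(w, Vec3{1, 0, 0}));
  v = cross(w, u);
}

static inline Vec3 hg_sample_dir(Vec3 w, double g, RNG &rng) {
  double cost = hg_sample_cost(g, rng.uni());
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * rng.uni();
  Vec3 u, v;
  onb(w, u, v);
  return normalize(cost * w + (sint * std::cos(phi)) * u +
                   (sint * std::sin(phi)) * v);
}

// ---------------------------------------------------------------------------
// Woodcock free-flight: first real collision along o + t*d at bin `im`.
// Returns true with hit distance and material index (0-based), false on
// escape.

static bool woodcock(const Pack &P, Vec3 o, Vec3 d, int im, RNG &rng,
                     double &thit, int &matk) {
  double t0, t1;
  if (!P.box_overlap(o, d, t0, t1)) return false;
  double mb = P.maj[im];
  if (mb <= 0) return false;
  double t = t0;
  for (;;) {
    t -= std::log(1.0 - rng.uni()) / mb;
    if (t >= t1) return false;
    int lab = P.label_at(o + t * d);
    double st = (lab > 0) ? P.st[im + (size_t)P.nb * (lab - 1)] : 0.0;
    if (st > 0 && rng.uni() * mb < st) {
      thit = t;
      matk = lab - 1;
      return true;
    }
  }
}

// Ratio-tracking transmittance along segment a -> b at bin `ib`.
static double transmit(const Pack &P, Vec3 a, Vec3 b, int ib, RNG &rng) {
  Vec3 d = b - a;
  double len = norm(d);
  if (len <= 0) return 1.0;
  d = (1.0 / len) * d;
  double t0, t1;
  if (!P.box_overlap(a, d, t0, t1)) return 1.0;
  if (t1 > len) t1 = len;
  if (t1 <= t0) return 1.0;
  double mb = P.maj[ib];
  if (mb <= 0) return 1.0;
  double tau = 1.0, t = t0;
  for (;;) {
    t -= std::log(1.0 - rng.uni()) / mb;
    if (t >= t1) return tau;
    int lab = P.label_at(a + t * d);
    double st = (lab > 0) ? P.st[ib + (size_t)P.nb * (lab - 1)] : 0.0;
    tau *= 1.0 - st / mb;
    if (tau <= 0) return 0.0;
  }
}

// Exact transmittance along a -> b: piecewise-constant voxel medium, so
// the attenuation line integral is computed exactly by DDA marching.
static double exact_tau(const Pack &P, Vec3 a, Vec3 b, int ib) {
  Vec3 d = b - a;
  double len = norm(d);
  if (len <= 0) return 1.0;
  d = (1.0 / len) * d;
  double t0, t1;
  if (!P.box_overlap(a, d, t0, t1)) return 1.0;
  if (t1 > len) t1 = len;
  if (t1 <= t0) return 1.0;
  double dd[3] = {d.x, d.y, d.z};
  double oo[3] = {a.x, a.y, a.z};
  double lo[3] = {P.origin.x, P.origin.y, P.origin.z};
  int dims[3] = {P.nx, P.ny, P.nz};
  // entry voxel (nudged inside)
  double tcur = t0;
  double integral = 0.0;
  int iv[3];
  double tnext[3], tdelta[3];
  int step[3];
  {
    double eps = 1e-12 * (t1 - t0 + 1.0);
    Vec3 pstart = a + (t0 + eps) * d;
    double pp[3] = {pstart.x, pstart.y, pstart.z};
    for (int ax = 0; ax < 3; ++ax) {
      iv[ax] = (int)std::floor((pp[ax] - lo[ax]) / P.spacing);
      if (iv[ax] < 0) iv[ax] = 0;
      if (iv[ax] > dims[ax] - 1) iv[ax] = dims[ax] - 1;
      if (std::fabs(dd[ax]) < 1e-15) {
        step[ax] = 0;
        tnext[ax] = 1e300;
        tdelta[ax] = 1e300;
      } else if (dd[ax] > 0) {
        step[ax] = 1;
        tnext[ax] = ((iv[ax] + 1) * P.spacing + lo[ax] - oo[ax]) / dd[ax];
        tdelta[ax] = P.spacing / dd[ax];
      } else {
        step[ax] = -1;
        tnext[ax] = (iv[ax] * P.spacing + lo[ax] - oo[ax]) / dd[ax];
        tdelta[ax] = -P.spacing / dd[ax];
      }
    }
  }
  for (;;) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double tstop = tnext[ax] < t1 ? tnext[ax] : t1;
    int lab = P.labels[iv[0] + (size_t)P.nx * (iv[1] + (size_t)P.ny * iv[2])];
    if (lab > 0) {
      integral += P.st[ib + (size_t)P.nb * (lab - 1)] * (tstop - tcur);
    }
    if (tnext[ax] >= t1) break;
    tcur = tnext[ax];
    tnext[ax] += tdelta[ax];
    iv[ax] += step[ax];
    if (iv[ax] < 0 || iv[ax] >= dims[ax]) break;
  }
  return std::exp(-integral);
}

// Next-event light connection at a vertex of material `matk` reached with
// direction `dir` at emission bin `im`. Samples lambda_x ~ L_e * mu_a^f
// and a light point; returns
//   phi * p_m(lm) * mu_a^f(lx) * f_p * L_e * G * tau_x * A / p(lx) p(x_n)
// which, with the categorical lambda_x pdf, collapses to
//   phi * p_m(lm) * f_p * G * tau_x * A * sum_b L_e(b) mu_a^f(b).
static double light_connection(const Pack &P, Vec3 pos, Vec3 dir, int matk,
                               int im, RNG &rng) {
  size_t col = (size_t)P.nb * matk;
  double wsum = 0.0;
  for (int b : P.le_bins) wsum += P.Le[b] * P.maf[b + col];
  if (wsum <= 0) return 0.0;
  double target = rng.uni() * wsum, acc = 0.0;
  int ix = P.le_bins.back();
  for (int b : P.le_bins) {
    acc += P.Le[b] * P.maf[b + col];
    if (acc >= target) { ix = b; break; }
  }
  double ua = rng.uni(), ub = rng.uni();
  Vec3 xl = P.lcorner + ua * P.le1 + ub * P.le2;
  Vec3 dv = xl - pos;
  double r2 = dot(dv, dv);
  if (r2 <= 0) return 0.0;
  double r = std::sqrt(r2);
  Vec3 wl = (1.0 / r) * dv;
  double cosl = -dot(P.lnormal, wl);
  if (cosl <= 0) return 0.0;  // behind the emitting face
  double G = cosl / r2;
  double tau = exact_tau(P, pos, xl, ix);
  double fp = hg_eval(P.g[matk], dot(dir, wl));
  return P.phi[matk] * P.pm[im + col] * fp * G * tau * P.larea * wsum;
}

// ---------------------------------------------------------------------------
// One camera path at emission bin `im` through pixel (px, py).
// Returns the radiance sample (0 for any path whose fluorescence
// visibility stays unset).

static double trace_one(const Pack &P, int px, int py, int im, RNG &rng,
                        bool jitter) {
  double sx = (px + (jitter ? rng.uni() : 0.5)) / P.W;
  double sy = (py + (jitter ? rng.uni() : 0.5)) / P.H;
  double aspect = (double)P.W / P.H;
  double uu = (2.0 * sx - 1.0) * P.tanhalf * aspect;
  double vv = (1.0 - 2.0 * sy) * P.tanhalf;
  Vec3 dir = normalize(P.cfwd + uu * P.cright + vv * P.cup);
  Vec3 pos = P.cpos;
  double tp = 1.0;
  double total = 0.0;
  int nvert = 0;

  for (;;) {
    double thit;
    int matk;
    if (!woodcock(P, pos, dir, im, rng, thit, matk)) return total;
    pos = pos + thit * dir;
    ++nvert;
    size_t col = (size_t)P.nb * matk;
    double st = P.st[im + col], ss = P.ss[im + col];
    double mua = P.ma[im + col], muaf = P.maf[im + col];

    if (P.nee_mode == 0) {
      // collision-driven next-event estimation: the expected fluorescence
      // contribution of this vertex, with the classification branch
      // marginalized analytically (selection probability mu_a^f / sigma_t
      // times the event weight; the mu_a^f(lambda_m) factors cancel)
      total += tp * light_connection(P, pos, dir, matk, im, rng) / st;
    }

    double u = rng.uni();
    if (u < ss / st) {
      // elastic scatter: wavelength preserved, HG importance weight = 1
      if (nvert >= P.max_bounces) return total;
      if (nvert >= P.rr_depth) {
        if (rng.uni() >= P.rr_floor) return total;
        tp /= P.rr_floor;
      }
      dir = hg_sample_dir(dir, P.g[matk], rng);
      continue;
    }
    // absorption: fluorescent with probability mu_a^f / mu_a, terminal
    // otherwise; either way the camera-side walk ends here (a valid path
    // holds a single inelastic vertex)
    if (mua <= 0) return total;
    bool fluor = rng.uni() < muaf / mua;
    if (P.nee_mode == 1 && fluor && muaf > 0) {
      // event-triggered variant (light sampled only at the fluorescence
      // event, vertex-selection probability divided out)
      total += tp * light_connection(P, pos, dir, matk, im, rng) / muaf;
    }
    return total;
  }
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trace(List pack, int px, int py, int bin0, int n, int seed,
                        bool jitter) {
  Pack P(pack);
  NumericVector out(n);
  uint64_t pix = (uint64_t)px + (uint64_t)P.W * py;
  for (int i = 0; i < n; ++i) {
    RNG rng((uint64_t)seed, pix, (uint64_t)i + 0x100000000ULL);
    out[i] = trace_one(P, px, py, bin0, rng, jitter);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_render(List pack, int spp, int nspec, int seed) {
  Pack P(pack);
  size_t npx = (size_t)P.W * P.H;
  NumericVector img(npx * P.nb);
  double *im = REAL(img);
  for (int py = 0; py < P.H; ++py) {
    for (int px = 0; px < P.W; ++px) {
      uint64_t pix = (uint64_t)px + (uint64_t)P.W * py;
      for (int s = 0; s < spp; ++s) {
        for (int k = 0; k < nspec; ++k) {
          RNG rng((uint64_t)seed, pix, (uint64_t)s * nspec + k);
          // stratified draw of the emission bin from the scene pdf
          double u = (k + rng.uni()) / nspec;
          int lo = 0, hi = P.nb - 1;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (P.scdf[mid] >= u) hi = mid; else lo = mid + 1;
          }
          int bin = lo;
          if (P.spdf[bin] <= 0) continue;
          double val = trace_one(P, px, py, bin, rng, true);
          if (val != 0.0)
            im[pix + npx * bin] += val / P.spdf[bin];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  double inv = 1.0 / ((double)spp * nspec);
  for (size_t i = 0; i < npx * (size_t)P.nb; ++i) im[i] *= inv;
  return img;
}

// [[Rcpp::export]]
NumericVector cpp_free_path(List pack, NumericVector origin,
                            NumericVector direction, int bin0, int n,
                            int seed) {
  Pack P(pack);
  Vec3 o = as_vec3(origin), d = normalize(as_vec3(direction));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    RNG rng((uint64_t)seed, 0xFEEDULL, (uint64_t)i);
    double thit;
    int matk;
    out[i] = woodcock(P, o, d, bin0, rng, thit, matk) ? thit : R_PosInf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_transmittance(List pack, NumericVector a, NumericVector b,
                                int bin0, int n, int seed) {
  Pack P(pack);
  Vec3 va = as_vec3(a), vb = as_vec3(b);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    RNG rng((uint64_t)seed, 0x7A0ULL, (uint64_t)i);
    out[i] = transmit(P, va, vb, bin0, rng);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_exact_tau(List pack, NumericVector a, NumericVector b,
                     int bin0) {
  Pack P(pack);
  return exact_tau(P, as_vec3(a), as_vec3(b), bin0);
}

// [[Rcpp::export]]
NumericMatrix cpp_hg_sample(double g, int n, int seed) {
  NumericMatrix out(n, 3);
  Vec3 w{0, 0, 1};
  for (int i = 0; i < n; ++i) {
    RNG rng((uint64_t)seed, 0x46ULL, (uint64_t)i);
    Vec3 d = hg_sample_dir(w, g, rng);
    out(i, 0) = d.x; out(i, 1) = d.y; out(i, 2) = d.z;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Solid voxelization by ray-crossing parity, computed per connected mesh
// component and OR-ed (so unions of overlapping closed components fill
// correctly). Ties (a scan ray meeting an edge or vertex) are resolved by
// deterministically jittering the ray origin and retrying.

struct VoxCtx {
  const double *vx, *vy, *vz;   // permuted vertex coords: a = scan axis
  int nface;
  const int *f0, *f1, *f2;      // 0-based vertex ids
  const int *comp;              // component id per face
};

// crossings of the scan line (b0, c0) for faces of component `cid`;
// returns false on a tie
static bool row_crossings(const VoxCtx &M, int cid, double b0, double c0,
                          std::vector<double> &xs) {
  xs.clear();
  for (int t = 0; t < M.nface; ++t) {
    if (M.comp[t] != cid) continue;
    int i0 = M.f0[t], i1 = M.f1[t], i2 = M.f2[t];
    double b1 = M.vy[i0] - b0, b2 = M.vy[i1] - b0, b3 = M.vy[i2] - b0;
    double c1 = M.vz[i0] - c0, c2 = M.vz[i1] - c0, c3 = M.vz[i2] - c0;
    // signed areas of sub-triangles with the origin
    double d1 = b1 * c2 - b2 * c1;
    double d2 = b2 * c3 - b3 * c2;
    double d3 = b3 * c1 - b1 * c3;
    bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
    bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
    if (pos && neg) continue;            // outside
    if (d1 == 0 || d2 == 0 || d3 == 0) return false;  // tie: edge/vertex hit
    double area = d1 + d2 + d3;
    if (area == 0) return false;         // degenerate projection
    double w0 = d2 / area, w1 = d3 / area, w2 = d1 / area;
    xs.push_back(w0 * M.vx[i0] + w1 * M.vx[i1] + w2 * M.vx[i2]);
  }
  if (xs.size() % 2 != 0) return false;  // open parity: treat as tie
  std::sort(xs.begin(), xs.end());
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector comp, IntegerVector dims,
                           NumericVector origin, double spacing, int axis) {
  int nv = V.nrow(), nf = F.nrow();
  // permute so the scan axis is first
  int pa = axis, pb = (axis + 1) % 3, pc = (axis + 2) % 3;
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = V(i, pa); vy[i] = V(i, pb); vz[i] = V(i, pc);
  }
  std::vector<int> f0(nf), f1(nf), f2(nf), cm(nf);
  for (int t = 0; t < nf; ++t) {
    f0[t] = F(t, 0) - 1; f1[t] = F(t, 1) - 1; f2[t] = F(t, 2) - 1;
    cm[t] = comp[t];
  }
  VoxCtx M{vx.data(), vy.data(), vz.data(), nf,
           f0.data(), f1.data(), f2.data(), cm.data()};
  std::vector<int> comps(cm.begin(), cm.end());
  std::sort(comps.begin(), comps.end());
  comps.erase(std::unique(comps.begin(), comps.end()), comps.end());

  int na = dims[pa], nbm = dims[pb], nc = dims[pc];
  double oa = origin[pa], ob = origin[pb], oc = origin[pc];
  IntegerVector out((size_t)dims[0] * dims[1] * dims[2]);
  int *o = INTEGER(out);
  // strides of the (x, y, z) output array for the permuted axes
  size_t stride[3] = {1, (size_t)dims[0], (size_t)dims[0] * dims[1]};
  size_t sa = stride[pa], sb = stride[pb], sc = stride[pc];

  std::vector<double> xs;
  for (int jc = 0; jc < nc; ++jc) {
    for (int jb = 0; jb < nbm; ++jb) {
      for (int cid : comps) {
        double b0 = ob + (jb + 0.5) * spacing;
        double c0 = oc + (jc + 0.5) * spacing;
        bool ok = false;
        for (int attempt = 0; attempt < 12 && !ok; ++attempt) {
          double eps = attempt * 0.01830951 * spacing;  // sub-voxel jitter
          ok = row_crossings(M, cid, b0 + eps, c0 + 1.31 * eps, xs);
        }
        if (!ok) continue;  // persistent degeneracy: skip component row
        for (size_t q = 0; q + 1 < xs.size(); q += 2) {
          // voxel centers oa + (i + 0.5) * spacing inside (xs[q], xs[q+1])
          int ilo = (int)std::ceil((xs[q] - oa) / spacing - 0.5);
          int ihi = (int)std::floor((xs[q + 1] - oa) / spacing - 0.5);
          if (ilo < 0) ilo = 0;
          if (ihi > na - 1) ihi = na - 1;
          for (int i = ilo; i <= ihi; ++i) {
            double ctr = oa + (i + 0.5) * spacing;
            if (ctr > xs[q] && ctr < xs[q + 1])
              o[(size_t)i * sa + (size_t)jb * sb + (size_t)jc * sc] = 1;
          }
        }
      }
    }
  }
  return out;
}
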