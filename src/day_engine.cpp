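// Compiled inner loop of the daily feeding bout.
//
// Semantics mirror the pure-R reference engine (step_school / consume_pellets)
// exactly: synchronous update in the fixed intra-step order
//   modes -> perception -> forces -> integration -> pellet sinking -> contact
// All randomness (random-movement directions, contested-pellet tie-breaks)
// comes from R's RNG stream, so runs are reproducible under set.seed().
//
// The O(n^2) field-of-view scan and the fish x pellet scans are the hot
// spots; they are hand-vectorized (SSE2 baseline with an AVX2 variant
// selected at run time) with fixed lane-combination order, so results are
// deterministic for a given build and CPU.  A scalar fallback covers
// non-x86 targets.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

#if defined(__x86_64__) || defined(__SSE2__)
#define SCHOOLFEED_SSE2 1
#include <emmintrin.h>
#if defined(__GNUC__)
#define SCHOOLFEED_AVX2 1
#include <immintrin.h>
#endif
#endif

namespace {

struct Params {
  double dt, radius, depth;
  double w1, w2, w3, w4, w5_standard, w5_feeding, w6;
  double cv_standard, cv_feeding;
  double sink_speed, pellet_mass, pellet_radius, contact_radius_factor;
  double fov_radius_factor, cos_dead_zone, force_scale, clamp_eps;
  bool isotropic;
};

Params read_params(const List& par) {
  Params p;
  p.dt = as<double>(par["dt"]);
  p.radius = as<double>(par["radius"]);
  p.depth = as<double>(par["depth"]);
  p.w1 = as<double>(par["w1"]);
  p.w2 = as<double>(par["w2"]);
  p.w3 = as<double>(par["w3"]);
  p.w4 = as<double>(par["w4"]);
  p.w5_standard = as<double>(par["w5_standard"]);
  p.w5_feeding = as<double>(par["w5_feeding"]);
  p.w6 = as<double>(par["w6"]);
  p.cv_standard = as<double>(par["cv_standard"]);
  p.cv_feeding = as<double>(par["cv_feeding"]);
  p.sink_speed = as<double>(par["sink_speed"]);
  p.pellet_mass = as<double>(par["pellet_mass"]);
  p.pellet_radius = as<double>(par["pellet_radius"]);
  p.contact_radius_factor = as<double>(par["contact_radius_factor"]);
  p.fov_radius_factor = as<double>(par["fov_radius_factor"]);
  p.cos_dead_zone = as<double>(par["cos_dead_zone"]);
  p.force_scale = as<double>(par["force_scale"]);
  p.clamp_eps = as<double>(par["clamp_eps"]);
  p.isotropic = as<bool>(par["isotropic"]);
  return p;
}

inline void random_unit(bool isotropic, double* u) {
  for (;;) {
    double a, b, c;
    if (isotropic) {
      a = norm_rand(); b = norm_rand(); c = norm_rand();
    } else {
      a = 2.0 * unif_rand() - 1.0;
      b = 2.0 * unif_rand() - 1.0;
      c = 2.0 * unif_rand() - 1.0;
    }
    double n2 = a * a + b * b + c * c;
    if (n2 > 1e-24) {
      double inv = 1.0 / std::sqrt(n2);
      u[0] = a * inv; u[1] = b * inv; u[2] = c * inv;
      return;
    }
  }
}

// accumulated field-of-view information for one focal fish
struct NeighborOut {
  double cnt, sx, sy, sz, svx, svy, svz;
  long nn;       // index of nearest in-view fish, -1 if none
  double nnd2;   // its squared distance
};

struct PelletNearest {
  long idx;      // index into the compacted live-pellet arrays, -1 if none
  double d2;
};

// ---------------------------------------------------------------------------
// scalar reference scans (portable fallback; also document the semantics)

NeighborOut neighbor_scan_scalar(long i, long n,
                                 const double* px, const double* py,
                                 const double* pz, const double* vx,
                                 const double* vy, const double* vz,
                                 double xi, double yi, double zi,
                                 double vxi, double vyi, double vzi,
                                 double ri2, double si2, double cos2) {
  NeighborOut o{0, 0, 0, 0, 0, 0, 0, -1, R_PosInf};
  const bool cone = si2 > 0;
  for (long j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = px[j] - xi, dy = py[j] - yi, dz = pz[j] - zi;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > ri2) continue;
    if (cone) {
      double dot = dx * vxi + dy * vyi + dz * vzi;
      if (dot < 0 && dot * dot > cos2 * d2 * si2) continue;  // rear dead cone
    }
    o.cnt += 1;
    o.sx += px[j]; o.sy += py[j]; o.sz += pz[j];
    o.svx += vx[j]; o.svy += vy[j]; o.svz += vz[j];
    if (d2 < o.nnd2) { o.nnd2 = d2; o.nn = j; }
  }
  return o;
}

PelletNearest pellet_nearest_scalar(long np, const double* qx,
                                    const double* qy, const double* qz,
                                    double xi, double yi, double zi) {
  PelletNearest o{-1, R_PosInf};
  for (long k = 0; k < np; ++k) {
    double dx = qx[k] - xi, dy = qy[k] - yi, dz = qz[k] - zi;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < o.d2) { o.d2 = d2; o.idx = k; }
  }
  return o;
}

void contact_collect_scalar(long np, const double* qx, const double* qy,
                            const double* qz, double xi, double yi, double zi,
                            double cr2, long fish,
                            std::vector<std::pair<long, long>>& out) {
  for (long k = 0; k < np; ++k) {
    double dx = qx[k] - xi, dy = qy[k] - yi, dz = qz[k] - zi;
    if (dx * dx + dy * dy + dz * dz <= cr2) out.emplace_back(k, fish);
  }
}

#ifdef SCHOOLFEED_SSE2
// ---------------------------------------------------------------------------
// SSE2 (x86-64 baseline) scans.  Lane partials are combined in a fixed
// order, so sums differ from the sequential scalar order only by benign
// floating-point reassociation; the nearest-element tie rule (smallest
// index wins on exact distance ties) matches the scalar scan.

inline __m128d blend_pd(__m128d mask, __m128d a, __m128d b) {
  return _mm_or_pd(_mm_and_pd(mask, a), _mm_andnot_pd(mask, b));
}

NeighborOut neighbor_scan_sse2(long i, long n,
                               const double* px, const double* py,
                               const double* pz, const double* vx,
                               const double* vy, const double* vz,
                               double xi, double yi, double zi,
                               double vxi, double vyi, double vzi,
                               double ri2, double si2, double cos2) {
  const bool cone = si2 > 0;
  const __m128d vxi2 = _mm_set1_pd(xi), vyi2 = _mm_set1_pd(yi),
                vzi2 = _mm_set1_pd(zi);
  const __m128d vvx = _mm_set1_pd(vxi), vvy = _mm_set1_pd(vyi),
                vvz = _mm_set1_pd(vzi);
  const __m128d vri2 = _mm_set1_pd(ri2);
  const __m128d vcs = _mm_set1_pd(cos2 * si2);
  const __m128d vone = _mm_set1_pd(1.0), vzero = _mm_setzero_pd();
  const __m128d vinf = _mm_set1_pd(R_PosInf);
  const __m128d viself = _mm_set1_pd((double)i);
  __m128d cnt = vzero, sx = vzero, sy = vzero, sz = vzero,
          svx = vzero, svy = vzero, svz = vzero;
  __m128d bestd = vinf, besti = _mm_set1_pd(-1.0);
  __m128d idx = _mm_set_pd(1.0, 0.0);
  const __m128d idxinc = _mm_set1_pd(2.0);
  long j = 0;
  for (; j + 2 <= n; j += 2, idx = _mm_add_pd(idx, idxinc)) {
    __m128d x = _mm_loadu_pd(px + j), y = _mm_loadu_pd(py + j),
            z = _mm_loadu_pd(pz + j);
    __m128d dx = _mm_sub_pd(x, vxi2), dy = _mm_sub_pd(y, vyi2),
            dz = _mm_sub_pd(z, vzi2);
    __m128d d2 = _mm_add_pd(_mm_add_pd(_mm_mul_pd(dx, dx), _mm_mul_pd(dy, dy)),
                            _mm_mul_pd(dz, dz));
    __m128d ok = _mm_cmple_pd(d2, vri2);
    ok = _mm_andnot_pd(_mm_cmpeq_pd(idx, viself), ok);
    if (cone) {
      __m128d dot = _mm_add_pd(
          _mm_add_pd(_mm_mul_pd(dx, vvx), _mm_mul_pd(dy, vvy)),
          _mm_mul_pd(dz, vvz));
      __m128d bad = _mm_and_pd(
          _mm_cmplt_pd(dot, vzero),
          _mm_cmpgt_pd(_mm_mul_pd(dot, dot), _mm_mul_pd(vcs, d2)));
      ok = _mm_andnot_pd(bad, ok);
    }
    cnt = _mm_add_pd(cnt, _mm_and_pd(ok, vone));
    sx = _mm_add_pd(sx, _mm_and_pd(ok, x));
    sy = _mm_add_pd(sy, _mm_and_pd(ok, y));
    sz = _mm_add_pd(sz, _mm_and_pd(ok, z));
    svx = _mm_add_pd(svx, _mm_and_pd(ok, _mm_loadu_pd(vx + j)));
    svy = _mm_add_pd(svy, _mm_and_pd(ok, _mm_loadu_pd(vy + j)));
    svz = _mm_add_pd(svz, _mm_and_pd(ok, _mm_loadu_pd(vz + j)));
    __m128d dok = blend_pd(ok, d2, vinf);
    __m128d lt = _mm_cmplt_pd(dok, bestd);
    bestd = blend_pd(lt, dok, bestd);
    besti = blend_pd(lt, idx, besti);
  }
  // lane combination in registers (avoids store-forwarding stalls)
  auto hsum2 = [](__m128d v) {
    return _mm_cvtsd_f64(_mm_add_sd(v, _mm_unpackhi_pd(v, v)));
  };
  NeighborOut o;
  o.cnt = hsum2(cnt);
  o.sx = hsum2(sx); o.sy = hsum2(sy); o.sz = hsum2(sz);
  o.svx = hsum2(svx); o.svy = hsum2(svy); o.svz = hsum2(svz);
  double bd[2] = { _mm_cvtsd_f64(bestd),
                   _mm_cvtsd_f64(_mm_unpackhi_pd(bestd, bestd)) };
  double bi[2] = { _mm_cvtsd_f64(besti),
                   _mm_cvtsd_f64(_mm_unpackhi_pd(besti, besti)) };
  o.nn = -1; o.nnd2 = R_PosInf;
  for (int k = 0; k < 2; ++k)
    if (bd[k] < o.nnd2 || (bd[k] == o.nnd2 && bi[k] >= 0 && bi[k] < (double)o.nn))
      { o.nnd2 = bd[k]; o.nn = (long)bi[k]; }
  // scalar tail (self index shifted into tail coordinates, -1 if not there)
  long ii = (i >= j) ? i - j : -1;
  NeighborOut t = neighbor_scan_scalar(ii, n - j, px + j, py + j, pz + j,
                                       vx + j, vy + j, vz + j,
                                       xi, yi, zi, vxi, vyi, vzi, ri2, si2,
                                       cos2);
  o.cnt += t.cnt; o.sx += t.sx; o.sy += t.sy; o.sz += t.sz;
  o.svx += t.svx; o.svy += t.svy; o.svz += t.svz;
  if (t.nn >= 0 && t.nnd2 < o.nnd2) { o.nnd2 = t.nnd2; o.nn = t.nn + j; }
  return o;
}

PelletNearest pellet_nearest_sse2(long np, const double* qx, const double* qy,
                                  const double* qz, double xi, double yi,
                                  double zi) {
  const __m128d vx = _mm_set1_pd(xi), vy = _mm_set1_pd(yi),
                vz = _mm_set1_pd(zi);
  __m128d bestd = _mm_set1_pd(R_PosInf), besti = _mm_set1_pd(-1.0);
  __m128d idx = _mm_set_pd(1.0, 0.0);
  const __m128d idxinc = _mm_set1_pd(2.0);
  long k = 0;
  for (; k + 2 <= np; k += 2, idx = _mm_add_pd(idx, idxinc)) {
    __m128d dx = _mm_sub_pd(_mm_loadu_pd(qx + k), vx);
    __m128d dy = _mm_sub_pd(_mm_loadu_pd(qy + k), vy);
    __m128d dz = _mm_sub_pd(_mm_loadu_pd(qz + k), vz);
    __m128d d2 = _mm_add_pd(_mm_add_pd(_mm_mul_pd(dx, dx), _mm_mul_pd(dy, dy)),
                            _mm_mul_pd(dz, dz));
    __m128d lt = _mm_cmplt_pd(d2, bestd);
    bestd = blend_pd(lt, d2, bestd);
    besti = blend_pd(lt, idx, besti);
  }
  double bd[2] = { _mm_cvtsd_f64(bestd),
                   _mm_cvtsd_f64(_mm_unpackhi_pd(bestd, bestd)) };
  double bi[2] = { _mm_cvtsd_f64(besti),
                   _mm_cvtsd_f64(_mm_unpackhi_pd(besti, besti)) };
  PelletNearest o{-1, R_PosInf};
  for (int l = 0; l < 2; ++l)
    if (bd[l] < o.d2 || (bd[l] == o.d2 && bi[l] >= 0 && bi[l] < (double)o.idx))
      { o.d2 = bd[l]; o.idx = (long)bi[l]; }
  PelletNearest t = pellet_nearest_scalar(np - k, qx + k, qy + k, qz + k,
                                          xi, yi, zi);
  if (t.idx >= 0 && t.d2 < o.d2) { o.d2 = t.d2; o.idx = t.idx + k; }
  return o;
}

void contact_collect_sse2(long np, const double* qx, const double* qy,
                          const double* qz, double xi, double yi, double zi,
                          double cr2, long fish,
                          std::vector<std::pair<long, long>>& out) {
  const __m128d vx = _mm_set1_pd(xi), vy = _mm_set1_pd(yi),
                vz = _mm_set1_pd(zi);
  const __m128d vcr2 = _mm_set1_pd(cr2);
  long k = 0;
  for (; k + 2 <= np; k += 2) {
    __m128d dx = _mm_sub_pd(_mm_loadu_pd(qx + k), vx);
    __m128d dy = _mm_sub_pd(_mm_loadu_pd(qy + k), vy);
    __m128d dz = _mm_sub_pd(_mm_loadu_pd(qz + k), vz);
    __m128d d2 = _mm_add_pd(_mm_add_pd(_mm_mul_pd(dx, dx), _mm_mul_pd(dy, dy)),
                            _mm_mul_pd(dz, dz));
    int m = _mm_movemask_pd(_mm_cmple_pd(d2, vcr2));
    if (m & 1) out.emplace_back(k, fish);
    if (m & 2) out.emplace_back(k + 1, fish);
  }
  for (; k < np; ++k) {
    double dx = qx[k] - xi, dy = qy[k] - yi, dz = qz[k] - zi;
    if (dx * dx + dy * dy + dz * dz <= cr2) out.emplace_back(k, fish);
  }
}
#endif  // SCHOOLFEED_SSE2

#ifdef SCHOOLFEED_AVX2
#pragma GCC push_options
#pragma GCC target("avx2,fma")

inline __m256d blend4_pd(__m256d mask, __m256d a, __m256d b) {
  return _mm256_blendv_pd(b, a, mask);
}

NeighborOut neighbor_scan_avx2(long i, long n,
                               const double* px, const double* py,
                               const double* pz, const double* vx,
                               const double* vy, const double* vz,
                               double xi, double yi, double zi,
                               double vxi, double vyi, double vzi,
                               double ri2, double si2, double cos2) {
  const bool cone = si2 > 0;
  const __m256d vxi4 = _mm256_set1_pd(xi), vyi4 = _mm256_set1_pd(yi),
                vzi4 = _mm256_set1_pd(zi);
  const __m256d vvx = _mm256_set1_pd(vxi), vvy = _mm256_set1_pd(vyi),
                vvz = _mm256_set1_pd(vzi);
  const __m256d vri2 = _mm256_set1_pd(ri2);
  const __m256d vcs = _mm256_set1_pd(cos2 * si2);
  const __m256d vone = _mm256_set1_pd(1.0), vzero = _mm256_setzero_pd();
  const __m256d vinf = _mm256_set1_pd(R_PosInf);
  const __m256d viself = _mm256_set1_pd((double)i);
  __m256d cnt = vzero, sx = vzero, sy = vzero, sz = vzero,
          svx = vzero, svy = vzero, svz = vzero;
  __m256d bestd = vinf, besti = _mm256_set1_pd(-1.0);
  __m256d idx = _mm256_set_pd(3.0, 2.0, 1.0, 0.0);
  const __m256d idxinc = _mm256_set1_pd(4.0);
  long j = 0;
  for (; j + 4 <= n; j += 4, idx = _mm256_add_pd(idx, idxinc)) {
    __m256d x = _mm256_loadu_pd(px + j), y = _mm256_loadu_pd(py + j),
            z = _mm256_loadu_pd(pz + j);
    __m256d dx = _mm256_sub_pd(x, vxi4), dy = _mm256_sub_pd(y, vyi4),
            dz = _mm256_sub_pd(z, vzi4);
    __m256d d2 = _mm256_fmadd_pd(dx, dx,
                 _mm256_fmadd_pd(dy, dy, _mm256_mul_pd(dz, dz)));
    __m256d ok = _mm256_cmp_pd(d2, vri2, _CMP_LE_OQ);
    ok = _mm256_andnot_pd(_mm256_cmp_pd(idx, viself, _CMP_EQ_OQ), ok);
    if (cone) {
      __m256d dot = _mm256_fmadd_pd(dx, vvx,
                    _mm256_fmadd_pd(dy, vvy, _mm256_mul_pd(dz, vvz)));
      __m256d bad = _mm256_and_pd(
          _mm256_cmp_pd(dot, vzero, _CMP_LT_OQ),
          _mm256_cmp_pd(_mm256_mul_pd(dot, dot), _mm256_mul_pd(vcs, d2),
                        _CMP_GT_OQ));
      ok = _mm256_andnot_pd(bad, ok);
    }
    cnt = _mm256_add_pd(cnt, _mm256_and_pd(ok, vone));
    sx = _mm256_add_pd(sx, _mm256_and_pd(ok, x));
    sy = _mm256_add_pd(sy, _mm256_and_pd(ok, y));
    sz = _mm256_add_pd(sz, _mm256_and_pd(ok, z));
    svx = _mm256_add_pd(svx, _mm256_and_pd(ok, _mm256_loadu_pd(vx + j)));
    svy = _mm256_add_pd(svy, _mm256_and_pd(ok, _mm256_loadu_pd(vy + j)));
    svz = _mm256_add_pd(svz, _mm256_and_pd(ok, _mm256_loadu_pd(vz + j)));
    __m256d dok = blend4_pd(ok, d2, vinf);
    __m256d lt = _mm256_cmp_pd(dok, bestd, _CMP_LT_OQ);
    bestd = blend4_pd(lt, dok, bestd);
    besti = blend4_pd(lt, idx, besti);
  }
  // lane combination in registers, fixed (lane0+lane1)+(lane2+lane3) order
  auto hsum = [](__m256d v) {
    __m128d lo = _mm256_castpd256_pd128(v);
    __m128d hi = _mm256_extractf128_pd(v, 1);
    __m128d p01 = _mm_add_sd(lo, _mm_unpackhi_pd(lo, lo));
    __m128d p23 = _mm_add_sd(hi, _mm_unpackhi_pd(hi, hi));
    return _mm_cvtsd_f64(_mm_add_sd(p01, p23));
  };
  auto lanes = [](__m256d v, double* out) {
    __m128d lo = _mm256_castpd256_pd128(v);
    __m128d hi = _mm256_extractf128_pd(v, 1);
    out[0] = _mm_cvtsd_f64(lo);
    out[1] = _mm_cvtsd_f64(_mm_unpackhi_pd(lo, lo));
    out[2] = _mm_cvtsd_f64(hi);
    out[3] = _mm_cvtsd_f64(_mm_unpackhi_pd(hi, hi));
  };
  NeighborOut o;
  o.cnt = hsum(cnt); o.sx = hsum(sx); o.sy = hsum(sy); o.sz = hsum(sz);
  o.svx = hsum(svx); o.svy = hsum(svy); o.svz = hsum(svz);
  double bd[4], bi[4];
  lanes(bestd, bd); lanes(besti, bi);
  o.nn = -1; o.nnd2 = R_PosInf;
  for (int k = 0; k < 4; ++k)
    if (bd[k] < o.nnd2 || (bd[k] == o.nnd2 && bi[k] >= 0 && bi[k] < (double)o.nn))
      { o.nnd2 = bd[k]; o.nn = (long)bi[k]; }
  // scalar tail, inlined (calling non-VEX code here would incur SSE/AVX
  // transition penalties on every scan)
  for (; j < n; ++j) {
    if (j == i) continue;
    double dx = px[j] - xi, dy = py[j] - yi, dz = pz[j] - zi;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > ri2) continue;
    if (cone) {
      double dot = dx * vxi + dy * vyi + dz * vzi;
      if (dot < 0 && dot * dot > cos2 * d2 * si2) continue;
    }
    o.cnt += 1;
    o.sx += px[j]; o.sy += py[j]; o.sz += pz[j];
    o.svx += vx[j]; o.svy += vy[j]; o.svz += vz[j];
    if (d2 < o.nnd2) { o.nnd2 = d2; o.nn = j; }
  }
  return o;
}

PelletNearest pellet_nearest_avx2(long np, const double* qx, const double* qy,
                                  const double* qz, double xi, double yi,
                                  double zi) {
  const __m256d vx = _mm256_set1_pd(xi), vy = _mm256_set1_pd(yi),
                vz = _mm256_set1_pd(zi);
  __m256d bestd = _mm256_set1_pd(R_PosInf), besti = _mm256_set1_pd(-1.0);
  __m256d idx = _mm256_set_pd(3.0, 2.0, 1.0, 0.0);
  const __m256d idxinc = _mm256_set1_pd(4.0);
  long k = 0;
  for (; k + 4 <= np; k += 4, idx = _mm256_add_pd(idx, idxinc)) {
    __m256d dx = _mm256_sub_pd(_mm256_loadu_pd(qx + k), vx);
    __m256d dy = _mm256_sub_pd(_mm256_loadu_pd(qy + k), vy);
    __m256d dz = _mm256_sub_pd(_mm256_loadu_pd(qz + k), vz);
    __m256d d2 = _mm256_fmadd_pd(dx, dx,
                 _mm256_fmadd_pd(dy, dy, _mm256_mul_pd(dz, dz)));
    __m256d lt = _mm256_cmp_pd(d2, bestd, _CMP_LT_OQ);
    bestd = blend4_pd(lt, d2, bestd);
    besti = blend4_pd(lt, idx, besti);
  }
  auto lanes = [](__m256d v, double* out) {
    __m128d lo = _mm256_castpd256_pd128(v);
    __m128d hi = _mm256_extractf128_pd(v, 1);
    out[0] = _mm_cvtsd_f64(lo);
    out[1] = _mm_cvtsd_f64(_mm_unpackhi_pd(lo, lo));
    out[2] = _mm_cvtsd_f64(hi);
    out[3] = _mm_cvtsd_f64(_mm_unpackhi_pd(hi, hi));
  };
  double bd[4], bi[4];
  lanes(bestd, bd); lanes(besti, bi);
  PelletNearest o{-1, R_PosInf};
  for (int l = 0; l < 4; ++l)
    if (bd[l] < o.d2 || (bd[l] == o.d2 && bi[l] >= 0 && bi[l] < (double)o.idx))
      { o.d2 = bd[l]; o.idx = (long)bi[l]; }
  for (; k < np; ++k) {
    double dx = qx[k] - xi, dy = qy[k] - yi, dz = qz[k] - zi;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < o.d2) { o.d2 = d2; o.idx = k; }
  }
  return o;
}

void contact_collect_avx2(long np, const double* qx, const double* qy,
                          const double* qz, double xi, double yi, double zi,
                          double cr2, long fish,
                          std::vector<std::pair<long, long>>& out) {
  const __m256d vx = _mm256_set1_pd(xi), vy = _mm256_set1_pd(yi),
                vz = _mm256_set1_pd(zi);
  const __m256d vcr2 = _mm256_set1_pd(cr2);
  long k = 0;
  for (; k + 4 <= np; k += 4) {
    __m256d dx = _mm256_sub_pd(_mm256_loadu_pd(qx + k), vx);
    __m256d dy = _mm256_sub_pd(_mm256_loadu_pd(qy + k), vy);
    __m256d dz = _mm256_sub_pd(_mm256_loadu_pd(qz + k), vz);
    __m256d d2 = _mm256_fmadd_pd(dx, dx,
                 _mm256_fmadd_pd(dy, dy, _mm256_mul_pd(dz, dz)));
    int m = _mm256_movemask_pd(_mm256_cmp_pd(d2, vcr2, _CMP_LE_OQ));
    if (m) {
      for (int l = 0; l < 4; ++l)
        if (m & (1 << l)) out.emplace_back(k + l, fish);
    }
  }
  for (; k < np; ++k) {
    double dx = qx[k] - xi, dy = qy[k] - yi, dz = qz[k] - zi;
    if (dx * dx + dy * dy + dz * dz <= cr2) out.emplace_back(k, fish);
  }
}
#pragma GCC pop_options
#endif  // SCHOOLFEED_AVX2

// runtime ISA selection (0 scalar, 1 SSE2, 2 AVX2)
int simd_level() {
  static int level = [] {
#ifdef SCHOOLFEED_AVX2
    if (__builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma"))
      return 2;
#endif
#ifdef SCHOOLFEED_SSE2
    return 1;
#else
    return 0;
#endif
  }();
  return level;
}

NeighborOut neighbor_scan(long i, long n, const double* px, const double* py,
                          const double* pz, const double* vx,
                          const double* vy, const double* vz,
                          double xi, double yi, double zi,
                          double vxi, double vyi, double vzi,
                          double ri2, double si2, double cos2) {
  switch (simd_level()) {
#ifdef SCHOOLFEED_AVX2
    case 2: return neighbor_scan_avx2(i, n, px, py, pz, vx, vy, vz, xi, yi,
                                      zi, vxi, vyi, vzi, ri2, si2, cos2);
#endif
#ifdef SCHOOLFEED_SSE2
    case 1: return neighbor_scan_sse2(i, n, px, py, pz, vx, vy, vz, xi, yi,
                                      zi, vxi, vyi, vzi, ri2, si2, cos2);
#endif
    default: return neighbor_scan_scalar(i, n, px, py, pz, vx, vy, vz, xi,
                                         yi, zi, vxi, vyi, vzi, ri2, si2,
                                         cos2);
  }
}

PelletNearest pellet_nearest(long np, const double* qx, const double* qy,
                             const double* qz, double xi, double yi,
                             double zi) {
  switch (simd_level()) {
#ifdef SCHOOLFEED_AVX2
    case 2: return pellet_nearest_avx2(np, qx, qy, qz, xi, yi, zi);
#endif
#ifdef SCHOOLFEED_SSE2
    case 1: return pellet_nearest_sse2(np, qx, qy, qz, xi, yi, zi);
#endif
    default: return pellet_nearest_scalar(np, qx, qy, qz, xi, yi, zi);
  }
}

void contact_collect(long np, const double* qx, const double* qy,
                     const double* qz, double xi, double yi, double zi,
                     double cr2, long fish,
                     std::vector<std::pair<long, long>>& out) {
  switch (simd_level()) {
#ifdef SCHOOLFEED_AVX2
    case 2: contact_collect_avx2(np, qx, qy, qz, xi, yi, zi, cr2, fish, out);
            return;
#endif
#ifdef SCHOOLFEED_SSE2
    case 1: contact_collect_sse2(np, qx, qy, qz, xi, yi, zi, cr2, fish, out);
            return;
#endif
    default: contact_collect_scalar(np, qx, qy, qz, xi, yi, zi, cr2, fish,
                                    out);
  }
}

// ---------------------------------------------------------------------------

struct Engine {
  long n;
  Params p;
  std::vector<double> px, py, pz, vx, vy, vz, mass, tl, intake, smax;
  std::vector<int> eaten;
  std::vector<char> feeding;              // mode at step start
  // live pellets, compacted (ascending original index)
  std::vector<double> qx, qy, qz;
  std::vector<long> qid;                  // 0-based original pellet index
  long n_pellets_total = 0;
  // scratch
  std::vector<double> fx, fy, fz, spd2, rad2;
  std::vector<std::pair<long, long>> contacts;  // (pellet, fish)
  double max_speed_excess = 0.0;

  void set_modes() {
    bool feed_present = !qx.empty();
    for (long i = 0; i < n; ++i)
      feeding[i] = (feed_present && intake[i] < smax[i]) ? 1 : 0;
  }

  // one synchronous step; f6 (n x 3, column-major) may be NULL -> draw
  void step(const double* f6, long step_no,
            std::vector<double>* ev_time, std::vector<int>* ev_fish,
            std::vector<int>* ev_pellet) {
    const double cos2 = p.cos_dead_zone * p.cos_dead_zone;
    const long np = (long)qx.size();
    const double* Px = px.data();
    const double* Py = py.data();
    const double* Pz = pz.data();
    const double* Vx = vx.data();
    const double* Vy = vy.data();
    const double* Vz = vz.data();
    for (long i = 0; i < n; ++i) {
      spd2[i] = Vx[i] * Vx[i] + Vy[i] * Vy[i] + Vz[i] * Vz[i];
      double r = p.fov_radius_factor * tl[i];
      rad2[i] = r * r;
    }
    for (long i = 0; i < n; ++i) {
      const double xi = Px[i], yi = Py[i], zi = Pz[i];
      const double vxi = Vx[i], vyi = Vy[i], vzi = Vz[i];
      NeighborOut nb = neighbor_scan(i, n, Px, Py, Pz, Vx, Vy, Vz,
                                     xi, yi, zi, vxi, vyi, vzi,
                                     rad2[i], spd2[i], cos2);
      double Fx = 0, Fy = 0, Fz = 0;
      if (nb.nn >= 0) {                    // separation from nearest in view
        double d = std::sqrt(nb.nnd2);
        if (d > 0) {
          double inv = p.w1 / d;
          Fx += (xi - Px[nb.nn]) * inv;
          Fy += (yi - Py[nb.nn]) * inv;
          Fz += (zi - Pz[nb.nn]) * inv;
        } else {                           // coincident: random direction
          double u[3]; random_unit(p.isotropic, u);
          Fx += p.w1 * u[0]; Fy += p.w1 * u[1]; Fz += p.w1 * u[2];
        }
      }
      if (nb.cnt > 0) {                    // cohesion + alignment
        double m = nb.cnt;
        double dx = nb.sx / m - xi, dy = nb.sy / m - yi, dz = nb.sz / m - zi;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d > 0) { Fx += p.w2 * dx / d; Fy += p.w2 * dy / d; Fz += p.w2 * dz / d; }
        double ax = nb.svx / m - vxi, ay = nb.svy / m - vyi,
               az = nb.svz / m - vzi;
        double a = std::sqrt(ax * ax + ay * ay + az * az);
        if (a > 0) { Fx += p.w3 * ax / a; Fy += p.w3 * ay / a; Fz += p.w3 * az / a; }
      }
      {                                    // boundary: wall, bottom, surface
        double r = std::sqrt(xi * xi + yi * yi);
        double dw = (r > 1e-12) ? p.radius - r : p.radius;
        double best = dw; int which = 0;
        if (zi < best) { best = zi; which = 1; }
        if (p.depth - zi < best) { best = p.depth - zi; which = 2; }
        if (best <= p.fov_radius_factor * tl[i]) {
          if (which == 0)      { Fx += -p.w4 * xi / r; Fy += -p.w4 * yi / r; }
          else if (which == 1) { Fz += p.w4; }
          else                 { Fz += -p.w4; }
        }
      }
      double w5 = feeding[i] ? p.w5_feeding : p.w5_standard;
      if (w5 != 0 && np > 0) {             // feed attraction, FOV-unrestricted
        PelletNearest pe = pellet_nearest(np, qx.data(), qy.data(), qz.data(),
                                          xi, yi, zi);
        if (pe.idx >= 0 && pe.d2 > 0) {
          double inv = w5 / std::sqrt(pe.d2);
          Fx += (qx[pe.idx] - xi) * inv;
          Fy += (qy[pe.idx] - yi) * inv;
          Fz += (qz[pe.idx] - zi) * inv;
        }
      }
      {                                    // random movement
        if (f6) {
          Fx += f6[i]; Fy += f6[n + i]; Fz += f6[2 * n + i];
        } else {
          double u[3];
          random_unit(p.isotropic, u);
          Fx += p.w6 * u[0]; Fy += p.w6 * u[1]; Fz += p.w6 * u[2];
        }
      }
      if (!std::isfinite(Fx) || !std::isfinite(Fy) || !std::isfinite(Fz))
        stop("non-finite swimming force (fish %d, step %d)", (int)(i + 1),
             (int)step_no);
      fx[i] = Fx; fy[i] = Fy; fz[i] = Fz;
    }
    // integrate all fish (semi-implicit Euler, speed cap, interior clamp)
    for (long i = 0; i < n; ++i) {
      double inv_m = p.force_scale / mass[i];
      double nvx = vx[i] + fx[i] * inv_m * p.dt;
      double nvy = vy[i] + fy[i] * inv_m * p.dt;
      double nvz = vz[i] + fz[i] * inv_m * p.dt;
      double vmax = (feeding[i] ? p.cv_feeding : p.cv_standard) * tl[i];
      double s2 = nvx * nvx + nvy * nvy + nvz * nvz;
      if (s2 > vmax * vmax) {
        double sc = vmax / std::sqrt(s2);
        nvx *= sc; nvy *= sc; nvz *= sc;
      }
      double nx = px[i] + nvx * p.dt;
      double ny = py[i] + nvy * p.dt;
      double nz = pz[i] + nvz * p.dt;
      double r = std::sqrt(nx * nx + ny * ny);
      double rmax = p.radius - p.clamp_eps;
      if (r > rmax) {
        double sc = rmax / r;
        nx *= sc; ny *= sc;
        double ex = nx / rmax, ey = ny / rmax;
        double vr = nvx * ex + nvy * ey;
        if (vr > 0) { nvx -= vr * ex; nvy -= vr * ey; }
      }
      if (nz < p.clamp_eps) { nz = p.clamp_eps; if (nvz < 0) nvz = 0; }
      if (nz > p.depth - p.clamp_eps) {
        nz = p.depth - p.clamp_eps; if (nvz > 0) nvz = 0;
      }
      double sp = std::sqrt(nvx * nvx + nvy * nvy + nvz * nvz);
      if (sp - vmax > max_speed_excess) max_speed_excess = sp - vmax;
      px[i] = nx; py[i] = ny; pz[i] = nz;
      vx[i] = nvx; vy[i] = nvy; vz[i] = nvz;
    }
    // pellets: sink, then contact consumption at post-move positions
    if (np > 0) {
      double dz = p.sink_speed * p.dt;
      for (long k = 0; k < np; ++k) {
        qz[k] -= dz;
        if (qz[k] < 0) qz[k] = 0;
      }
      // collect fish-pellet contacts (fish in feeding mode at step start)
      contacts.clear();
      for (long i = 0; i < n; ++i) {
        if (!feeding[i]) continue;
        double cr = p.pellet_radius + p.contact_radius_factor * tl[i];
        contact_collect(np, qx.data(), qy.data(), qz.data(),
                        px[i], py[i], pz[i], cr * cr, i, contacts);
      }
      if (!contacts.empty()) {
        std::sort(contacts.begin(), contacts.end());
        std::vector<char> dead(np, 0);
        size_t a = 0;
        double t_now = step_no * p.dt;
        std::vector<long> cand;
        while (a < contacts.size()) {
          size_t b = a;
          long k = contacts[a].first;
          while (b < contacts.size() && contacts[b].first == k) ++b;
          // eligible: still below satiation cap right now
          cand.clear();
          for (size_t c = a; c < b; ++c) {
            long i = contacts[c].second;
            if (intake[i] < smax[i]) cand.push_back(i);
          }
          if (!cand.empty()) {
            long who = cand[0];
            if (cand.size() > 1) {
              long idx = (long)(unif_rand() * (double)cand.size());
              if (idx >= (long)cand.size()) idx = (long)cand.size() - 1;
              who = cand[idx];
            }
            dead[k] = 1;
            intake[who] += p.pellet_mass;
            eaten[who] += 1;
            if (ev_time) {
              ev_time->push_back(t_now);
              ev_fish->push_back((int)who + 1);
              ev_pellet->push_back((int)qid[k] + 1);
            }
          }
          a = b;
        }
        // compact the live-pellet arrays (preserves ascending id order)
        long w = 0;
        for (long k = 0; k < np; ++k) {
          if (dead[k]) continue;
          qx[w] = qx[k]; qy[w] = qy[k]; qz[w] = qz[k]; qid[w] = qid[k];
          ++w;
        }
        qx.resize(w); qy.resize(w); qz.resize(w); qid.resize(w);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List run_feeding_day_cpp(NumericMatrix pos, NumericMatrix vel,
                         NumericVector mass, NumericVector tl,
                         NumericVector smax,
                         NumericMatrix pellet_xyz, LogicalVector pellet_alive,
                         List par, int n_steps, bool stop_when_consumed,
                         bool record_events,
                         Nullable<NumericMatrix> f6 = R_NilValue) {
  RNGScope scope;
  Engine e;
  e.n = pos.nrow();
  e.p = read_params(par);
  const long n = e.n;
  e.px.assign(pos.begin(), pos.begin() + n);
  e.py.assign(pos.begin() + n, pos.begin() + 2 * n);
  e.pz.assign(pos.begin() + 2 * n, pos.begin() + 3 * n);
  e.vx.assign(vel.begin(), vel.begin() + n);
  e.vy.assign(vel.begin() + n, vel.begin() + 2 * n);
  e.vz.assign(vel.begin() + 2 * n, vel.begin() + 3 * n);
  e.mass.assign(mass.begin(), mass.end());
  e.tl.assign(tl.begin(), tl.end());
  e.smax.assign(smax.begin(), smax.end());
  e.intake.assign(n, 0.0);
  e.eaten.assign(n, 0);
  e.feeding.assign(n, 0);
  e.fx.assign(n, 0.0); e.fy.assign(n, 0.0); e.fz.assign(n, 0.0);
  e.spd2.assign(n, 0.0); e.rad2.assign(n, 0.0);

  e.n_pellets_total = pellet_xyz.nrow();
  std::vector<double> pellet_z_final(e.n_pellets_total);
  for (long k = 0; k < e.n_pellets_total; ++k) {
    pellet_z_final[k] = pellet_xyz(k, 2);
    if (pellet_alive[k]) {
      e.qx.push_back(pellet_xyz(k, 0));
      e.qy.push_back(pellet_xyz(k, 1));
      e.qz.push_back(pellet_xyz(k, 2));
      e.qid.push_back(k);
    }
  }

  const double* f6p = nullptr;
  NumericMatrix f6m;
  if (f6.isNotNull()) {
    f6m = as<NumericMatrix>(f6);
    if (f6m.nrow() != n || f6m.ncol() != 3)
      stop("f6 must be an n x 3 matrix");
    f6p = f6m.begin();
  }

  std::vector<double> ev_time;
  std::vector<int> ev_fish, ev_pellet;
  int completion_step = 0, steps_run = 0;
  for (int s = 1; s <= n_steps; ++s) {
    e.set_modes();
    e.step(f6p, s,
           record_events ? &ev_time : nullptr,
           record_events ? &ev_fish : nullptr,
           record_events ? &ev_pellet : nullptr);
    steps_run = s;
    if (e.n_pellets_total > 0 && e.qx.empty() && completion_step == 0)
      completion_step = s;
    if (stop_when_consumed && e.qx.empty()) break;
  }

  NumericMatrix out_pos(n, 3), out_vel(n, 3);
  for (long i = 0; i < n; ++i) {
    out_pos(i, 0) = e.px[i]; out_pos(i, 1) = e.py[i]; out_pos(i, 2) = e.pz[i];
    out_vel(i, 0) = e.vx[i]; out_vel(i, 1) = e.vy[i]; out_vel(i, 2) = e.vz[i];
  }
  LogicalVector out_alive(e.n_pellets_total, false);
  for (size_t k = 0; k < e.qid.size(); ++k) {
    out_alive[e.qid[k]] = true;
    pellet_z_final[e.qid[k]] = e.qz[k];
  }
  NumericMatrix events((int)ev_time.size(), 3);
  for (size_t r = 0; r < ev_time.size(); ++r) {
    events(r, 0) = ev_time[r];
    events(r, 1) = ev_fish[r];
    events(r, 2) = ev_pellet[r];
  }
  LogicalVector mode_feeding(n);
  for (long i = 0; i < n; ++i) mode_feeding[i] = e.feeding[i] != 0;
  return List::create(
    _["pos"] = out_pos, _["vel"] = out_vel,
    _["intake"] = NumericVector(e.intake.begin(), e.intake.end()),
    _["pellets_eaten"] = IntegerVector(e.eaten.begin(), e.eaten.end()),
    _["mode_feeding"] = mode_feeding,
    _["pellet_alive"] = out_alive,
    _["pellet_z"] = NumericVector(pellet_z_final.begin(), pellet_z_final.end()),
    _["completion_step"] = completion_step,
    _["steps_run"] = steps_run,
    _["max_speed_excess"] = e.max_speed_excess,
    _["events"] = events);
}
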