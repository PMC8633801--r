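#ifndef VASCTREE_GEOM_H
#define VASCTREE_GEOM_H

#include <cmath>
#include <algorithm>

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
static inline Vec3 vscale(const Vec3 &a, double s) {
  return {a.x * s, a.y * s, a.z * s};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// distance from point p to segment [a, b]
static inline double point_seg_dist(const Vec3 &p, const Vec3 &a, const Vec3 &b) {
  Vec3 ab = vsub(b, a);
  double l2 = vdot(ab, ab);
  if (l2 <= 0.0) return vnorm(vsub(p, a));
  double t = vdot(vsub(p, a), ab) / l2;
  t = std::max(0.0, std::min(1.0, t));
  Vec3 c = vadd(a, vscale(ab, t));
  return vnorm(vsub(p, c));
}

// minimum distance between segments [p1,q1] and [p2,q2]
// (standard clamped closest-point computation, Ericson-style)
static inline double seg_seg_dist(const Vec3 &p1, const Vec3 &q1,
                                  const Vec3 &p2, const Vec3 &q2) {
  Vec3 d1 = vsub(q1, p1), d2 = vsub(q2, p2), r = vsub(p1, p2);
  double a = vdot(d1, d1), e = vdot(d2, d2), f = vdot(d2, r);
  double s, t;
  const double EPS = 1e-300;
  if (a <= EPS && e <= EPS) return vnorm(r);
  if (a <= EPS) {
    s = 0.0;
    t = std::max(0.0, std::min(1.0, f / e));
  } else {
    double c = vdot(d1, r);
    if (e <= EPS) {
      t = 0.0;
      s = std::max(0.0, std::min(1.0, -c / a));
    } else {
      double b = vdot(d1, d2);
      double denom = a * e - b * b;
      s = (denom > 0.0) ? std::max(0.0, std::min(1.0, (b * f - c * e) / denom))
                        : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::max(0.0, std::min(1.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::max(0.0, std::min(1.0, (b - c) / a));
      }
    }
  }
  Vec3 c1 = vadd(p1, vscale(d1, s));
  Vec3 c2 = vadd(p2, vscale(d2, t));
  return vnorm(vsub(c1, c2));
}

// Moeller-Trumbore ray/triangle intersection; returns true and t when the ray
// origin+t*dir (t > 0) crosses triangle (v0,v1,v2). 'grazing' is set when the
// hit is numerically too close to an edge or the ray is near-parallel, in
// which case the caller should retry with another direction.
static inline bool ray_triangle(const Vec3 &orig, const Vec3 &dir,
                                const Vec3 &v0, const Vec3 &v1, const Vec3 &v2,
                                double &t, bool &grazing) {
  const double EPS = 1e-12;
  grazing = false;
  Vec3 e1 = vsub(v1, v0), e2 = vsub(v2, v0);
  Vec3 h = vcross(dir, e2);
  double det = vdot(e1, h);
  double scale = vnorm(e1) * vnorm(e2);
  if (std::fabs(det) < EPS * scale) {
    grazing = true;
    return false;
  }
  double inv = 1.0 / det;
  Vec3 s = vsub(orig, v0);
  double u = vdot(s, h) * inv;
  Vec3 q = vcross(s, e1);
  double v = vdot(dir, q) * inv;
  double w = 1.0 - u - v;
  const double BEPS = 1e-10;
  if (u < -BEPS || v < -BEPS || w < -BEPS) return false;
  t = vdot(e2, q) * inv;
  if (t <= 0.0) return false;
  if (u < BEPS || v < BEPS || w < BEPS || std::fabs(t) < BEPS) grazing = true;
  return true;
}

#endif
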