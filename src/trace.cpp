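// Quasi-Monte-Carlo light transport over a triangle soup.
//
// Rays are launched downward from an emitter plane above the scene and
// followed through ideal-diffuse reflection/transmission events; at every
// hit the surface absorbs (1 - R - T) of the ray weight for the struck
// side. A median-split BVH accelerates intersection. The generator is a
// per-ray-seeded PCG32 so results are bit-reproducible for a fixed seed
// regardless of scheduling.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator*(double s, V3 a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline V3 norm(V3 a) {
  double l = std::sqrt(dot(a, a));
  return v3(a.x / l, a.y / l, a.z / l);
}

// PCG32 (O'Neill); one independent stream per ray
struct PCG {
  uint64_t state, inc;
  PCG(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uni() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

struct Tri {
  V3 p0, e1, e2, n;  // n = unit front normal (right-hand winding)
  int surf;          // 0-based surface index
};

struct BBox {
  V3 lo, hi;
  void grow(V3 p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
};

struct Node {
  BBox box;
  int left, right;   // children, or -1 for leaf
  int start, count;  // range into the ordered triangle index array
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<int> order;
  std::vector<Node> nodes;

  int build(int start, int count, std::vector<V3>& centroids) {
    Node nd;
    nd.box.lo = v3(1e30, 1e30, 1e30);
    nd.box.hi = v3(-1e30, -1e30, -1e30);
    for (int i = start; i < start + count; ++i) {
      const Tri& t = tris[order[i]];
      nd.box.grow(t.p0);
      nd.box.grow(t.p0 + t.e1);
      nd.box.grow(t.p0 + t.e2);
    }
    if (count <= 4) {
      nd.left = nd.right = -1;
      nd.start = start;
      nd.count = count;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    V3 ext = nd.box.hi - nd.box.lo;
    int axis = (ext.x > ext.y && ext.x > ext.z) ? 0 : (ext.y > ext.z ? 1 : 2);
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int a, int b) {
                       const V3& ca = centroids[a];
                       const V3& cb = centroids[b];
                       return axis == 0 ? ca.x < cb.x : (axis == 1 ? ca.y < cb.y : ca.z < cb.z);
                     });
    int self = (int)nodes.size();
    nd.start = -1; nd.count = 0; nd.left = nd.right = -2;
    nodes.push_back(nd);
    int l = build(start, mid - start, centroids);
    int r = build(mid, start + count - mid, centroids);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void init(const NumericMatrix& v, const IntegerVector& surf) {
    int n = v.nrow() / 3;
    tris.resize(n);
    order.resize(n);
    std::vector<V3> centroids(n);
    for (int i = 0; i < n; ++i) {
      V3 a = v3(v(3 * i, 0), v(3 * i, 1), v(3 * i, 2));
      V3 b = v3(v(3 * i + 1, 0), v(3 * i + 1, 1), v(3 * i + 1, 2));
      V3 c = v3(v(3 * i + 2, 0), v(3 * i + 2, 1), v(3 * i + 2, 2));
      tris[i].p0 = a;
      tris[i].e1 = b - a;
      tris[i].e2 = c - a;
      V3 nn = cross(tris[i].e1, tris[i].e2);
      double l = std::sqrt(dot(nn, nn));
      tris[i].n = l > 0 ? v3(nn.x / l, nn.y / l, nn.z / l) : v3(0, 0, 1);
      tris[i].surf = surf[i] - 1;
      order[i] = i;
      centroids[i] = v3((a.x + b.x + c.x) / 3, (a.y + b.y + c.y) / 3, (a.z + b.z + c.z) / 3);
    }
    nodes.reserve(2 * n);
    build(0, n, centroids);
  }

  static inline bool hit_box(const BBox& b, V3 o, V3 inv, double tmax) {
    double t0 = 1e-9, t1 = tmax;
    double tx0 = (b.lo.x - o.x) * inv.x, tx1 = (b.hi.x - o.x) * inv.x;
    if (inv.x < 0) std::swap(tx0, tx1);
    t0 = std::max(t0, tx0); t1 = std::min(t1, tx1);
    double ty0 = (b.lo.y - o.y) * inv.y, ty1 = (b.hi.y - o.y) * inv.y;
    if (inv.y < 0) std::swap(ty0, ty1);
    t0 = std::max(t0, ty0); t1 = std::min(t1, ty1);
    double tz0 = (b.lo.z - o.z) * inv.z, tz1 = (b.hi.z - o.z) * inv.z;
    if (inv.z < 0) std::swap(tz0, tz1);
    t0 = std::max(t0, tz0); t1 = std::min(t1, tz1);
    return t0 <= t1;
  }

  // Moller-Trumbore; returns triangle index or -1, t in *tout
  int intersect(V3 o, V3 d, double* tout) const {
    V3 inv = v3(1.0 / (d.x != 0 ? d.x : 1e-300),
                1.0 / (d.y != 0 ? d.y : 1e-300),
                1.0 / (d.z != 0 ? d.z : 1e-300));
    double best_t = 1e30;
    int best = -1;
    int stack[64];
    int sp = 0;
    stack[sp++] = 0;
    while (sp) {
      const Node& nd = nodes[stack[--sp]];
      if (!hit_box(nd.box, o, inv, best_t)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          const Tri& t = tris[order[i]];
          V3 pvec = cross(d, t.e2);
          double det = dot(t.e1, pvec);
          if (std::fabs(det) < 1e-14) continue;
          double invdet = 1.0 / det;
          V3 tvec = o - t.p0;
          double u = dot(tvec, pvec) * invdet;
          if (u < 0 || u > 1) continue;
          V3 qvec = cross(tvec, t.e1);
          double vv = dot(d, qvec) * invdet;
          if (vv < 0 || u + vv > 1) continue;
          double tt = dot(t.e2, qvec) * invdet;
          if (tt > 1e-7 && tt < best_t) {
            best_t = tt;
            best = order[i];
          }
        }
      } else {
        stack[sp++] = nd.left;
        stack[sp++] = nd.right;
      }
    }
    *tout = best_t;
    return best;
  }
};

// cosine-weighted hemisphere direction around unit axis
inline V3 cosine_dir(V3 axis, PCG& rng) {
  double u1 = rng.uni(), u2 = rng.uni();
  double r = std::sqrt(u1);
  double phi = 2 * M_PI * u2;
  double zloc = std::sqrt(std::max(0.0, 1 - u1));
  V3 t = std::fabs(axis.x) < 0.9 ? norm(cross(axis, v3(1, 0, 0)))
                                 : norm(cross(axis, v3(0, 1, 0)));
  V3 b = cross(axis, t);
  return norm((r * std::cos(phi)) * t + (r * std::sin(phi)) * b + zloc * axis);
}

double halton(uint32_t i, uint32_t base) {
  double f = 1.0, r = 0.0;
  while (i > 0) {
    f /= base;
    r += f * (i % base);
    i /= base;
  }
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".trace_cpp")]]
List trace_cpp(NumericMatrix v, IntegerVector surf, NumericMatrix optics,
               double q0, NumericVector emitter, int n_rays, int seed,
               int mode, NumericVector sun_dir, int max_bounces,
               double weight_floor, int n_batches, int sampler) {
  if (v.nrow() == 0) stop("empty scene");
  BVH bvh;
  bvh.init(v, surf);
  int nsurf = optics.nrow();
  std::vector<double> absorbed(nsurf, 0.0);
  NumericMatrix absorbed_batch(n_batches, nsurf);
  std::vector<double> escaped_batch(n_batches, 0.0);

  double x0 = emitter[0], x1 = emitter[1], y0 = emitter[2], y1 = emitter[3];
  double ztop = emitter[4];
  double area = (x1 - x0) * (y1 - y0);
  double w0 = q0 * area / n_rays;

  V3 cdir = v3(sun_dir[0], sun_dir[1], sun_dir[2]);
  if (mode == 1) cdir = norm(cdir);

  int gx = (int)std::ceil(std::sqrt((double)n_rays));

  for (int i = 0; i < n_rays; ++i) {
    PCG rng((uint64_t)seed, (uint64_t)i * 2u + 1u);
    int batch = i % n_batches;
    double px, py;
    if (sampler == 1) {  // low-discrepancy: scrambled Halton (2,3)
      double sx = halton((uint32_t)i + 1u, 2u) + rng.uni() * 1e-3;
      double sy = halton((uint32_t)i + 1u, 3u) + rng.uni() * 1e-3;
      px = x0 + (sx - std::floor(sx)) * (x1 - x0);
      py = y0 + (sy - std::floor(sy)) * (y1 - y0);
    } else {             // jittered stratified grid
      int cx = i % gx, cy = (i / gx) % gx;
      px = x0 + (cx + rng.uni()) / gx * (x1 - x0);
      py = y0 + (cy + rng.uni()) / gx * (y1 - y0);
    }
    V3 o = v3(px, py, ztop);
    V3 d;
    if (mode == 1) {
      d = cdir;
    } else {
      d = cosine_dir(v3(0, 0, -1), rng);
    }
    double w = w0;
    for (int b = 0; b <= max_bounces; ++b) {
      double t;
      int hit = bvh.intersect(o, d, &t);
      if (hit < 0) {
        escaped_batch[batch] += w;
        break;
      }
      const Tri& tr = bvh.tris[hit];
      double c = dot(d, tr.n);
      bool front = c < 0;
      int s = tr.surf;
      double R = front ? optics(s, 0) : optics(s, 2);
      double T = front ? optics(s, 1) : optics(s, 3);
      double a = 1.0 - R - T;
      absorbed[s] += w * a;
      absorbed_batch(batch, s) += w * a;
      w *= (R + T);
      if (w <= 0) break;
      if (w < weight_floor || b == max_bounces) {
        escaped_batch[batch] += w;
        break;
      }
      V3 hp = o + t * d;
      bool reflect = rng.uni() < R / (R + T);
      // reflection returns to the incoming side, transmission continues
      V3 axis;
      if (reflect) axis = front ? tr.n : v3(-tr.n.x, -tr.n.y, -tr.n.z);
      else axis = front ? v3(-tr.n.x, -tr.n.y, -tr.n.z) : tr.n;
      d = cosine_dir(axis, rng);
      o = hp + 1e-7 * axis;
    }
  }

  double escaped = 0;
  for (double e : escaped_batch) escaped += e;
  return List::create(
      _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
      _["absorbed_batch"] = absorbed_batch,
      _["escaped"] = escaped,
      _["escaped_batch"] = NumericVector(escaped_batch.begin(), escaped_batch.end()),
      _["emitted"] = w0 * n_rays,
      _["emitter_area"] = area);
}
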