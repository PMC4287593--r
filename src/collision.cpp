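// Geometric kernels: triangle-triangle intersection, AABB-tree build and
// query, an exhaustive all-pairs reference, and marching-tetrahedra
// isosurface extraction.  Hot paths live here; everything returns plain R
// vectors/matrices so results stay serializable.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline void vsub(double* r, const double* a, const double* b) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
static inline void vcross(double* r, const double* a, const double* b) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ---- coplanar 2D overlap via separating axes (inclusive: touching counts) --

static void project2(const double* p, int i0, int i1, double* q) {
  q[0] = p[i0]; q[1] = p[i1];
}

static bool tri2d_separated_by_edges(const double t1[3][2], const double t2[3][2]) {
  for (int e = 0; e < 3; ++e) {
    double ex = t1[(e + 1) % 3][0] - t1[e][0];
    double ey = t1[(e + 1) % 3][1] - t1[e][1];
    // axis perpendicular to edge
    double ax = -ey, ay = ex;
    double mn1 = 1e300, mx1 = -1e300, mn2 = 1e300, mx2 = -1e300;
    for (int k = 0; k < 3; ++k) {
      double p1 = ax * t1[k][0] + ay * t1[k][1];
      double p2 = ax * t2[k][0] + ay * t2[k][1];
      mn1 = std::min(mn1, p1); mx1 = std::max(mx1, p1);
      mn2 = std::min(mn2, p2); mx2 = std::max(mx2, p2);
    }
    if (mx1 < mn2 || mx2 < mn1) return true;
  }
  return false;
}

static bool coplanar_tri_tri(const double* N,
                             const double* V0, const double* V1, const double* V2,
                             const double* U0, const double* U1, const double* U2) {
  // drop the dominant normal axis
  double a[3] = { std::fabs(N[0]), std::fabs(N[1]), std::fabs(N[2]) };
  int i0, i1;
  if (a[0] >= a[1] && a[0] >= a[2]) { i0 = 1; i1 = 2; }
  else if (a[1] >= a[2])            { i0 = 0; i1 = 2; }
  else                              { i0 = 0; i1 = 1; }
  double t1[3][2], t2[3][2];
  project2(V0, i0, i1, t1[0]); project2(V1, i0, i1, t1[1]); project2(V2, i0, i1, t1[2]);
  project2(U0, i0, i1, t2[0]); project2(U1, i0, i1, t2[1]); project2(U2, i0, i1, t2[2]);
  if (tri2d_separated_by_edges(t1, t2)) return false;
  if (tri2d_separated_by_edges(t2, t1)) return false;
  return true;
}

// ---- Moller-style interval test ------------------------------------------

static inline void isect_interval(double VV0, double VV1, double VV2,
                                  double D0, double D1, double D2,
                                  double* i0, double* i1) {
  *i0 = VV0 + (VV1 - VV0) * D0 / (D0 - D1);
  *i1 = VV0 + (VV2 - VV0) * D0 / (D0 - D2);
}

// returns true when the (closed) triangles intersect
static bool tri_tri_overlap(const double* V0, const double* V1, const double* V2,
                            const double* U0, const double* U1, const double* U2) {
  const double EPS = 1e-12;
  double E1[3], E2[3], N1[3], N2[3], D[3];

  vsub(E1, V1, V0); vsub(E2, V2, V0); vcross(N1, E1, E2);
  double d1 = -vdot(N1, V0);
  double du0 = vdot(N1, U0) + d1, du1 = vdot(N1, U1) + d1, du2 = vdot(N1, U2) + d1;
  if (std::fabs(du0) < EPS) du0 = 0.0;
  if (std::fabs(du1) < EPS) du1 = 0.0;
  if (std::fabs(du2) < EPS) du2 = 0.0;
  if (du0 > 0 && du1 > 0 && du2 > 0) return false;
  if (du0 < 0 && du1 < 0 && du2 < 0) return false;

  vsub(E1, U1, U0); vsub(E2, U2, U0); vcross(N2, E1, E2);
  double d2 = -vdot(N2, U0);
  double dv0 = vdot(N2, V0) + d2, dv1 = vdot(N2, V1) + d2, dv2 = vdot(N2, V2) + d2;
  if (std::fabs(dv0) < EPS) dv0 = 0.0;
  if (std::fabs(dv1) < EPS) dv1 = 0.0;
  if (std::fabs(dv2) < EPS) dv2 = 0.0;
  if (dv0 > 0 && dv1 > 0 && dv2 > 0) return false;
  if (dv0 < 0 && dv1 < 0 && dv2 < 0) return false;

  vcross(D, N1, N2);
  double maxc = std::fabs(D[0]); int index = 0;
  if (std::fabs(D[1]) > maxc) { maxc = std::fabs(D[1]); index = 1; }
  if (std::fabs(D[2]) > maxc) { maxc = std::fabs(D[2]); index = 2; }

  double vp0 = V0[index], vp1 = V1[index], vp2 = V2[index];
  double up0 = U0[index], up1 = U1[index], up2 = U2[index];

  double isect1[2], isect2v[2];

  // triangle V against plane of U
  {
    double D0 = dv0, D1 = dv1, D2 = dv2;
    double D0D1 = D0 * D1, D0D2 = D0 * D2;
    if (D0D1 > 0)      isect_interval(vp2, vp0, vp1, D2, D0, D1, &isect1[0], &isect1[1]);
    else if (D0D2 > 0) isect_interval(vp1, vp0, vp2, D1, D0, D2, &isect1[0], &isect1[1]);
    else if (D1 * D2 > 0 || D0 != 0)
                       isect_interval(vp0, vp1, vp2, D0, D1, D2, &isect1[0], &isect1[1]);
    else if (D1 != 0)  isect_interval(vp1, vp0, vp2, D1, D0, D2, &isect1[0], &isect1[1]);
    else if (D2 != 0)  isect_interval(vp2, vp0, vp1, D2, D0, D1, &isect1[0], &isect1[1]);
    else return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);
  }
  // triangle U against plane of V
  {
    double D0 = du0, D1 = du1, D2 = du2;
    double D0D1 = D0 * D1, D0D2 = D0 * D2;
    if (D0D1 > 0)      isect_interval(up2, up0, up1, D2, D0, D1, &isect2v[0], &isect2v[1]);
    else if (D0D2 > 0) isect_interval(up1, up0, up2, D1, D0, D2, &isect2v[0], &isect2v[1]);
    else if (D1 * D2 > 0 || D0 != 0)
                       isect_interval(up0, up1, up2, D0, D1, D2, &isect2v[0], &isect2v[1]);
    else if (D1 != 0)  isect_interval(up1, up0, up2, D1, D0, D2, &isect2v[0], &isect2v[1]);
    else if (D2 != 0)  isect_interval(up2, up0, up1, D2, D0, D1, &isect2v[0], &isect2v[1]);
    else return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);
  }

  if (isect1[0] > isect1[1]) std::swap(isect1[0], isect1[1]);
  if (isect2v[0] > isect2v[1]) std::swap(isect2v[0], isect2v[1]);
  if (isect1[1] < isect2v[0] || isect2v[1] < isect1[0]) return false;
  return true;
}

// ---- helpers shared by BVH / brute force ---------------------------------

static std::vector<double> transform_vertices(const NumericMatrix& V,
                                              const NumericMatrix& R,
                                              const NumericVector& t) {
  int n = V.nrow();
  std::vector<double> out(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    double x = V(i, 0), y = V(i, 1), z = V(i, 2);
    out[3 * (size_t)i + 0] = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + t[0];
    out[3 * (size_t)i + 1] = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + t[1];
    out[3 * (size_t)i + 2] = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + t[2];
  }
  return out;
}

static inline void get_tri(const NumericMatrix& V, const IntegerMatrix& F, int tri,
                           double* a, double* b, double* c) {
  int i0 = F(tri, 0) - 1, i1 = F(tri, 1) - 1, i2 = F(tri, 2) - 1;
  a[0] = V(i0, 0); a[1] = V(i0, 1); a[2] = V(i0, 2);
  b[0] = V(i1, 0); b[1] = V(i1, 1); b[2] = V(i1, 2);
  c[0] = V(i2, 0); c[1] = V(i2, 1); c[2] = V(i2, 2);
}

static inline void get_tri_vec(const std::vector<double>& V, const IntegerMatrix& F, int tri,
                               double* a, double* b, double* c) {
  size_t i0 = (size_t)(F(tri, 0) - 1), i1 = (size_t)(F(tri, 1) - 1), i2 = (size_t)(F(tri, 2) - 1);
  for (int k = 0; k < 3; ++k) {
    a[k] = V[3 * i0 + k]; b[k] = V[3 * i1 + k]; c[k] = V[3 * i2 + k];
  }
}

// ---- BVH construction -----------------------------------------------------

struct BuildNode {
  double mn[3], mx[3];
  int left, right;   // 0-based child node ids, -1 for leaf
  int start, count;  // range into the triangle order array (leaves only)
};

// Axis-aligned box tree over mesh triangles, median split on the longest
// centroid axis.  Returned as flat arrays (1-based indices) so the tree is a
// plain R list.
// [[Rcpp::export]]
List bvh_build_cpp(NumericMatrix V, IntegerMatrix F, int leaf_size) {
  int nf = F.nrow();
  if (nf < 1) stop("mesh has no faces");
  if (leaf_size < 1) leaf_size = 1;

  std::vector<double> cx(nf), cy(nf), cz(nf);
  std::vector<double> bmn(3 * (size_t)nf), bmx(3 * (size_t)nf);
  for (int i = 0; i < nf; ++i) {
    double a[3], b[3], c[3];
    get_tri(V, F, i, a, b, c);
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(a[k], std::min(b[k], c[k]));
      double mx = std::max(a[k], std::max(b[k], c[k]));
      bmn[3 * (size_t)i + k] = mn;
      bmx[3 * (size_t)i + k] = mx;
    }
    cx[i] = (a[0] + b[0] + c[0]) / 3.0;
    cy[i] = (a[1] + b[1] + c[1]) / 3.0;
    cz[i] = (a[2] + b[2] + c[2]) / 3.0;
  }

  std::vector<int> order(nf);
  for (int i = 0; i < nf; ++i) order[i] = i;
  std::vector<BuildNode> nodes;
  nodes.reserve(2 * nf / std::max(1, leaf_size) + 4);

  // iterative build with an explicit worklist; each entry fills nodes[id]
  struct Task { int id, lo, hi; };
  std::vector<Task> work;
  nodes.push_back(BuildNode());
  work.push_back({0, 0, nf});
  const double* cen[3] = { cx.data(), cy.data(), cz.data() };

  while (!work.empty()) {
    Task tk = work.back(); work.pop_back();
    BuildNode nd;
    for (int k = 0; k < 3; ++k) { nd.mn[k] = 1e300; nd.mx[k] = -1e300; }
    double cmn[3] = {1e300, 1e300, 1e300}, cmx[3] = {-1e300, -1e300, -1e300};
    for (int i = tk.lo; i < tk.hi; ++i) {
      int t = order[i];
      for (int k = 0; k < 3; ++k) {
        nd.mn[k] = std::min(nd.mn[k], bmn[3 * (size_t)t + k]);
        nd.mx[k] = std::max(nd.mx[k], bmx[3 * (size_t)t + k]);
        cmn[k] = std::min(cmn[k], cen[k][t]);
        cmx[k] = std::max(cmx[k], cen[k][t]);
      }
    }
    int cnt = tk.hi - tk.lo;
    if (cnt <= leaf_size) {
      nd.left = nd.right = -1;
      nd.start = tk.lo; nd.count = cnt;
      nodes[tk.id] = nd;
      continue;
    }
    int axis = 0;
    double best = cmx[0] - cmn[0];
    for (int k = 1; k < 3; ++k)
      if (cmx[k] - cmn[k] > best) { best = cmx[k] - cmn[k]; axis = k; }
    int mid = tk.lo + cnt / 2;
    const double* ca = cen[axis];
    std::nth_element(order.begin() + tk.lo, order.begin() + mid, order.begin() + tk.hi,
                     [&](int a, int b) { return ca[a] < ca[b]; });
    nd.left = (int)nodes.size();
    nd.right = nd.left + 1;
    nd.start = tk.lo; nd.count = cnt;
    nodes[tk.id] = nd;
    nodes.push_back(BuildNode());
    nodes.push_back(BuildNode());
    work.push_back({nd.left, tk.lo, mid});
    work.push_back({nd.right, mid, tk.hi});
  }

  int nn = (int)nodes.size();
  NumericMatrix node_min(nn, 3), node_max(nn, 3);
  IntegerVector left(nn), right(nn), start(nn), count(nn);
  for (int i = 0; i < nn; ++i) {
    for (int k = 0; k < 3; ++k) {
      node_min(i, k) = nodes[i].mn[k];
      node_max(i, k) = nodes[i].mx[k];
    }
    left[i]  = nodes[i].left  < 0 ? 0 : nodes[i].left + 1;
    right[i] = nodes[i].right < 0 ? 0 : nodes[i].right + 1;
    start[i] = nodes[i].start + 1;
    count[i] = nodes[i].count;
  }
  IntegerVector ord(nf);
  for (int i = 0; i < nf; ++i) ord[i] = order[i] + 1;
  return List::create(_["node_min"] = node_min, _["node_max"] = node_max,
                      _["left"] = left, _["right"] = right,
                      _["start"] = start, _["count"] = count,
                      _["order"] = ord, _["n_faces"] = nf);
}

struct TreeView {
  NumericMatrix mn, mx;
  IntegerVector left, right, start, count, order;
  explicit TreeView(List bvh)
      : mn(as<NumericMatrix>(bvh["node_min"])),
        mx(as<NumericMatrix>(bvh["node_max"])),
        left(as<IntegerVector>(bvh["left"])),
        right(as<IntegerVector>(bvh["right"])),
        start(as<IntegerVector>(bvh["start"])),
        count(as<IntegerVector>(bvh["count"])),
        order(as<IntegerVector>(bvh["order"])) {}
};

// refit an AABB under a rigid transform (R, t): rotate center, grow half
// extents by |R| * h
static inline void refit_box(const double mn[3], const double mx[3],
                             const NumericMatrix& R, const NumericVector& t,
                             double omn[3], double omx[3]) {
  double c[3], h[3];
  for (int k = 0; k < 3; ++k) {
    c[k] = 0.5 * (mn[k] + mx[k]);
    h[k] = 0.5 * (mx[k] - mn[k]);
  }
  for (int i = 0; i < 3; ++i) {
    double ci = R(i, 0) * c[0] + R(i, 1) * c[1] + R(i, 2) * c[2] + t[i];
    double hi = std::fabs(R(i, 0)) * h[0] + std::fabs(R(i, 1)) * h[1] +
                std::fabs(R(i, 2)) * h[2];
    omn[i] = ci - hi; omx[i] = ci + hi;
  }
}

// Contacts between two posed meshes; Rrel/trel map B-local into A-local
// coordinates.  Returns a k x 2 matrix of 1-based (triA, triB) indices.
// [[Rcpp::export]]
IntegerMatrix bvh_collide_cpp(List bvhA, NumericMatrix VA, IntegerMatrix FA,
                              List bvhB, NumericMatrix VB, IntegerMatrix FB,
                              NumericMatrix Rrel, NumericVector trel,
                              bool first_only) {
  TreeView A(bvhA), B(bvhB);
  std::vector<double> VB2 = transform_vertices(VB, Rrel, trel);

  std::vector<std::pair<int, int> > contacts;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, 0));
  double bmn[3], bmx[3];

  while (!stack.empty()) {
    int a = stack.back().first, b = stack.back().second;
    stack.pop_back();
    double amn[3], amx[3];
    for (int k = 0; k < 3; ++k) { amn[k] = A.mn(a, k); amx[k] = A.mx(a, k); }
    double rb_mn[3], rb_mx[3];
    for (int k = 0; k < 3; ++k) { bmn[k] = B.mn(b, k); bmx[k] = B.mx(b, k); }
    refit_box(bmn, bmx, Rrel, trel, rb_mn, rb_mx);
    bool overlap = true;
    for (int k = 0; k < 3; ++k)
      if (amx[k] < rb_mn[k] || rb_mx[k] < amn[k]) { overlap = false; break; }
    if (!overlap) continue;

    bool leafA = A.left[a] == 0, leafB = B.left[b] == 0;
    if (leafA && leafB) {
      for (int i = 0; i < A.count[a]; ++i) {
        int ta = A.order[A.start[a] - 1 + i] - 1;
        double a0[3], a1[3], a2[3];
        get_tri(VA, FA, ta, a0, a1, a2);
        for (int j = 0; j < B.count[b]; ++j) {
          int tb = B.order[B.start[b] - 1 + j] - 1;
          double b0[3], b1[3], b2[3];
          get_tri_vec(VB2, FB, tb, b0, b1, b2);
          if (tri_tri_overlap(a0, a1, a2, b0, b1, b2)) {
            contacts.push_back(std::make_pair(ta + 1, tb + 1));
            if (first_only) goto done;
          }
        }
      }
    } else if (leafB || (!leafA && A.count[a] >= B.count[b])) {
      stack.push_back(std::make_pair(A.left[a] - 1, b));
      stack.push_back(std::make_pair(A.right[a] - 1, b));
    } else {
      stack.push_back(std::make_pair(a, B.left[b] - 1));
      stack.push_back(std::make_pair(a, B.right[b] - 1));
    }
  }
done:
  IntegerMatrix out((int)contacts.size(), 2);
  for (size_t i = 0; i < contacts.size(); ++i) {
    out((int)i, 0) = contacts[i].first;
    out((int)i, 1) = contacts[i].second;
  }
  return out;
}

// Exhaustive all-triangle-pairs intersection; the reference the tree query
// is tested against.
// [[Rcpp::export]]
IntegerMatrix tri_collide_brute_cpp(NumericMatrix VA, IntegerMatrix FA,
                                    NumericMatrix VB, IntegerMatrix FB,
                                    NumericMatrix Rrel, NumericVector trel) {
  std::vector<double> VB2 = transform_vertices(VB, Rrel, trel);
  std::vector<std::pair<int, int> > contacts;
  int na = FA.nrow(), nb = FB.nrow();
  for (int i = 0; i < na; ++i) {
    double a0[3], a1[3], a2[3];
    get_tri(VA, FA, i, a0, a1, a2);
    for (int j = 0; j < nb; ++j) {
      double b0[3], b1[3], b2[3];
      get_tri_vec(VB2, FB, j, b0, b1, b2);
      if (tri_tri_overlap(a0, a1, a2, b0, b1, b2))
        contacts.push_back(std::make_pair(i + 1, j + 1));
    }
  }
  IntegerMatrix out((int)contacts.size(), 2);
  for (size_t i = 0; i < contacts.size(); ++i) {
    out((int)i, 0) = contacts[i].first;
    out((int)i, 1) = contacts[i].second;
  }
  return out;
}

// ---- marching tetrahedra --------------------------------------------------

// cube corner bit layout: c0=(0,0,0) c1=(1,0,0) c2=(1,1,0) c3=(0,1,0)
//                         c4=(0,0,1) c5=(1,0,1) c6=(1,1,1) c7=(0,1,1)
static const int CUBE_OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// six tetrahedra sharing the 0-6 diagonal; face diagonals match between
// neighbouring cells, which keeps the extracted surface watertight
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // xyz triples
  std::vector<int> faces;      // 0-based triples
};

static int edge_point(MTState& st, uint64_t g1, double v1, const double p1[3],
                      uint64_t g2, double v2, const double p2[3], double level) {
  uint64_t a = g1, b = g2;
  const double* pa = p1; const double* pb = p2;
  double va = v1, vb = v2;
  if (a > b) { std::swap(a, b); std::swap(va, vb); std::swap(pa, pb); }
  uint64_t key = (a << 32) | b;
  std::unordered_map<uint64_t, int>::iterator it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double s = (level - va) / (vb - va);
  int id = (int)(st.verts.size() / 3);
  for (int k = 0; k < 3; ++k) st.verts.push_back(pa[k] + s * (pb[k] - pa[k]));
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState& st, int e0, int e1, int e2, const double inside_pt[3]) {
  // orient so the normal points away from the interior
  double* p0 = &st.verts[3 * (size_t)e0];
  double* p1 = &st.verts[3 * (size_t)e1];
  double* p2 = &st.verts[3 * (size_t)e2];
  double u[3], v[3], n[3], d[3];
  vsub(u, p1, p0); vsub(v, p2, p0); vcross(n, u, v);
  double cen[3] = { (p0[0] + p1[0] + p2[0]) / 3.0,
                    (p0[1] + p1[1] + p2[1]) / 3.0,
                    (p0[2] + p1[2] + p2[2]) / 3.0 };
  vsub(d, cen, inside_pt);
  if (vdot(n, d) >= 0) {
    st.faces.push_back(e0); st.faces.push_back(e1); st.faces.push_back(e2);
  } else {
    st.faces.push_back(e0); st.faces.push_back(e2); st.faces.push_back(e1);
  }
}

// Isosurface of a scalar field sampled on a regular grid (vals in
// x-fastest order), via tetrahedral decomposition of each cell.
// [[Rcpp::export]]
List marching_tets_cpp(NumericVector vals, IntegerVector dims,
                       NumericVector origin, double spacing, double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("grid must have at least 2 points per axis");
  MTState st;
  uint64_t gid[8];
  double gv[8], gp[8][3];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE_OFF[c][0], jj = j + CUBE_OFF[c][1], kk = k + CUBE_OFF[c][2];
          gid[c] = (uint64_t)ii + (uint64_t)nx * ((uint64_t)jj + (uint64_t)ny * (uint64_t)kk);
          gv[c] = vals[(R_xlen_t)gid[c]];
          gp[c][0] = origin[0] + spacing * ii;
          gp[c][1] = origin[1] + spacing * jj;
          gp[c][2] = origin[2] + spacing * kk;
        }
        for (int t = 0; t < 6; ++t) {
          int tv[4] = { TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3] };
          int in[4], nin = 0, nout = 0, outv[4];
          for (int m = 0; m < 4; ++m) {
            if (gv[tv[m]] > level) in[nin++] = tv[m];
            else outv[nout++] = tv[m];
          }
          if (nin == 0 || nin == 4) continue;
          double ipt[3] = {0, 0, 0};
          for (int m = 0; m < nin; ++m)
            for (int kk2 = 0; kk2 < 3; ++kk2) ipt[kk2] += gp[in[m]][kk2] / nin;
          if (nin == 1) {
            int a = in[0];
            int e0 = edge_point(st, gid[a], gv[a], gp[a], gid[outv[0]], gv[outv[0]], gp[outv[0]], level);
            int e1 = edge_point(st, gid[a], gv[a], gp[a], gid[outv[1]], gv[outv[1]], gp[outv[1]], level);
            int e2 = edge_point(st, gid[a], gv[a], gp[a], gid[outv[2]], gv[outv[2]], gp[outv[2]], level);
            emit_tri(st, e0, e1, e2, ipt);
          } else if (nin == 3) {
            int a = outv[0];
            int e0 = edge_point(st, gid[a], gv[a], gp[a], gid[in[0]], gv[in[0]], gp[in[0]], level);
            int e1 = edge_point(st, gid[a], gv[a], gp[a], gid[in[1]], gv[in[1]], gp[in[1]], level);
            int e2 = edge_point(st, gid[a], gv[a], gp[a], gid[in[2]], gv[in[2]], gp[in[2]], level);
            emit_tri(st, e0, e1, e2, ipt);
          } else { // nin == 2
            int a = in[0], b = in[1], c = outv[0], d = outv[1];
            int eac = edge_point(st, gid[a], gv[a], gp[a], gid[c], gv[c], gp[c], level);
            int ead = edge_point(st, gid[a], gv[a], gp[a], gid[d], gv[d], gp[d], level);
            int ebd = edge_point(st, gid[b], gv[b], gp[b], gid[d], gv[d], gp[d], level);
            int ebc = edge_point(st, gid[b], gv[b], gp[b], gid[c], gv[c], gp[c], level);
            emit_tri(st, eac, ead, ebd, ipt);
            emit_tri(st, eac, ebd, ebc, ipt);
          }
        }
      }

  int nv = (int)(st.verts.size() / 3), nf = (int)(st.faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = st.verts[3 * (size_t)i + k];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = st.faces[3 * (size_t)i + k] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}
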