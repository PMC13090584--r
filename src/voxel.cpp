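#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Voxel arrays arrive as R arrays with dim = c(nz, ny, nx) (column-major, so
// the linear index is z + nz*(y + ny*x)). Scan order throughout is
// lexicographic in (z, y, x): z outermost, x innermost.

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

struct Offsets {
  std::vector<int> dz, dy, dx;
};

static Offsets make_offsets(int connectivity) {
  Offsets o;
  int maxsum = (connectivity == 6) ? 1 : (connectivity == 18 ? 2 : 3);
  for (int z = -1; z <= 1; z++)
    for (int y = -1; y <= 1; y++)
      for (int x = -1; x <= 1; x++) {
        int s = std::abs(z) + std::abs(y) + std::abs(x);
        if (s == 0 || s > maxsum) continue;
        o.dz.push_back(z); o.dy.push_back(y); o.dx.push_back(x);
      }
  return o;
}

// [[Rcpp::export]]
IntegerVector label_components_3d(IntegerVector mask, IntegerVector dims,
                                  int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels((R_xlen_t)nz * ny * nx);
  Offsets off = make_offsets(connectivity);
  const int nn = (int)off.dz.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        if (mask[i] == 0 || labels[i] != 0) continue;
        next++;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur % nz);
          int rest = (int)(cur / nz);
          int cy = rest % ny;
          int cx = rest / ny;
          for (int k = 0; k < nn; k++) {
            int z2 = cz + off.dz[k], y2 = cy + off.dy[k], x2 = cx + off.dx[k];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              continue;
            R_xlen_t j = vidx(z2, y2, x2, nz, ny);
            if (mask[j] != 0 && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  labels.attr("n_components") = next;
  return labels;
}

// ---- topology-preserving thinning -------------------------------------------
// A foreground voxel is "simple" (removable without changing topology in the
// (26, 6) digital topology) iff its 26-neighbourhood contains exactly one
// 26-connected foreground component, and the background restricted to the
// 18-neighbourhood has exactly one 6-connected component touching a face
// neighbour (Malandain & Bertrand characterization).

static int count_fg_components_26(const bool nb[27]) {
  // nb indexed by (dz+1) + 3*(dy+1) + 9*(dx+1); center (index 13) excluded
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comps++;
    std::vector<int> st;
    st.push_back(i);
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int z = -1; z <= 1; z++)
        for (int y = -1; y <= 1; y++)
          for (int x = -1; x <= 1; x++) {
            int z2 = cz + z, y2 = cy + y, x2 = cx + x;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
            int j = z2 + 3 * y2 + 9 * x2;
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  return comps;
}

static int count_bg_components_6(const bool nb[27]) {
  // background 6-components within the 18-neighbourhood that touch a face
  // neighbour of the center
  bool in18[27], seen[27] = {false};
  for (int i = 0; i < 27; i++) {
    int dz = i % 3 - 1, dy = (i / 3) % 3 - 1, dx = i / 9 - 1;
    int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
    in18[i] = (s >= 1 && s <= 2);
  }
  int comps = 0;
  for (int i = 0; i < 27; i++) {
    int dz = i % 3 - 1, dy = (i / 3) % 3 - 1, dx = i / 9 - 1;
    if (std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;  // face nbrs
    if (nb[i] || seen[i]) continue;
    comps++;
    std::vector<int> st;
    st.push_back(i);
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      const int fz[6] = {-1, 1, 0, 0, 0, 0};
      const int fy[6] = {0, 0, -1, 1, 0, 0};
      const int fx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; k++) {
        int z2 = cz + fz[k], y2 = cy + fy[k], x2 = cx + fx[k];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        int j = z2 + 3 * y2 + 9 * x2;
        if (!in18[j] || seen[j] || nb[j]) continue;
        seen[j] = true;
        st.push_back(j);
      }
    }
  }
  return comps;
}

// [[Rcpp::export]]
IntegerVector thin_3d(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out = clone(mask);
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          R_xlen_t i = vidx(z, y, x, nz, ny);
          if (out[i] == 0) continue;
          int nfg = 0;
          bool border = false;
          for (int dz = -1; dz <= 1; dz++)
            for (int dy = -1; dy <= 1; dy++)
              for (int dx = -1; dx <= 1; dx++) {
                int z2 = z + dz, y2 = y + dy, x2 = x + dx;
                bool fg = false;
                if (z2 >= 0 && z2 < nz && y2 >= 0 && y2 < ny && x2 >= 0 && x2 < nx)
                  fg = out[vidx(z2, y2, x2, nz, ny)] != 0;
                nb[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = fg;
                if (!(dz == 0 && dy == 0 && dx == 0)) {
                  if (fg) nfg++;
                  if (!fg && std::abs(dz) + std::abs(dy) + std::abs(dx) == 1)
                    border = true;
                }
              }
          if (!border) continue;       // interior voxel
          if (nfg <= 1) continue;      // curve endpoint: keep
          nb[13] = false;
          if (count_fg_components_26(nb) != 1) continue;
          if (count_bg_components_6(nb) != 1) continue;
          out[i] = 0;  // simple point: sequential removal preserves topology
          changed = true;
        }
  }
  return out;
}

// ---- mesh geometry ----------------------------------------------------------

struct V3 {
  double x, y, z;
};
static inline V3 sub(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// minimum distance from point p to triangle (a,b,c)
static double pt_tri_dist(V3 p, V3 a, V3 b, V3 c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { V3 d = sub(p, a); return std::sqrt(dot(d, d)); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { V3 d = sub(p, b); return std::sqrt(dot(d, d)); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    V3 q = {a.x + v * ab.x, a.y + v * ab.y, a.z + v * ab.z};
    V3 d = sub(p, q); return std::sqrt(dot(d, d));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { V3 d = sub(p, c); return std::sqrt(dot(d, d)); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    V3 q = {a.x + w * ac.x, a.y + w * ac.y, a.z + w * ac.z};
    V3 d = sub(p, q); return std::sqrt(dot(d, d));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 bc = sub(c, b);
    V3 q = {b.x + w * bc.x, b.y + w * bc.y, b.z + w * bc.z};
    V3 d = sub(p, q); return std::sqrt(dot(d, d));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = {a.x + ab.x * v + ac.x * w, a.y + ab.y * v + ac.y * w,
          a.z + ab.z * v + ac.z * w};
  V3 d = sub(p, q);
  return std::sqrt(dot(d, d));
}

// [[Rcpp::export]]
NumericVector point_mesh_distance(NumericMatrix points, NumericMatrix verts,
                                  IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    V3 p = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; f++) {
      V3 a = {verts(faces(f, 0), 0), verts(faces(f, 0), 1), verts(faces(f, 0), 2)};
      V3 b = {verts(faces(f, 1), 0), verts(faces(f, 1), 1), verts(faces(f, 1), 2)};
      V3 c = {verts(faces(f, 2), 0), verts(faces(f, 2), 1), verts(faces(f, 2), 2)};
      double d = pt_tri_dist(p, a, b, c);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector point_cloud_min_distance(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; i++) {
    double px = query(i, 0), py = query(i, 1), pz = query(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nr; j++) {
      double dx = px - ref(j, 0), dy = py - ref(j, 1), dz = pz - ref(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Ray-parity containment. Points within `eps` of the surface count as inside.
// Several candidate ray directions are tried per point; a direction is
// rejected when any intersection is ambiguous (grazing or near an edge).

// [[Rcpp::export]]
LogicalVector points_in_mesh(NumericMatrix points, NumericMatrix verts,
                             IntegerMatrix faces, double eps) {
  const int np = points.nrow(), nf = faces.nrow();
  const int ndir = 5;
  const double dirs[ndir][3] = {
      {0.998831, 0.0327642, 0.0355572},
      {0.0327642, 0.998831, 0.0355572},
      {0.0355572, 0.0327642, 0.998831},
      {0.577350, 0.577350, 0.577350},
      {0.267261, 0.534522, 0.801784}};
  LogicalVector out(np);
  NumericVector surf = point_mesh_distance(points, verts, faces);
  for (int i = 0; i < np; i++) {
    if (surf[i] <= eps) { out[i] = true; continue; }
    V3 o = {points(i, 0), points(i, 1), points(i, 2)};
    bool decided = false;
    for (int a = 0; a < ndir && !decided; a++) {
      V3 d = {dirs[a][0], dirs[a][1], dirs[a][2]};
      int crossings = 0;
      bool ambiguous = false;
      for (int f = 0; f < nf; f++) {
        V3 va = {verts(faces(f, 0), 0), verts(faces(f, 0), 1), verts(faces(f, 0), 2)};
        V3 vb = {verts(faces(f, 1), 0), verts(faces(f, 1), 1), verts(faces(f, 1), 2)};
        V3 vc = {verts(faces(f, 2), 0), verts(faces(f, 2), 1), verts(faces(f, 2), 2)};
        V3 e1 = sub(vb, va), e2 = sub(vc, va);
        V3 pvec = cross(d, e2);
        double det = dot(e1, pvec);
        if (std::fabs(det) < 1e-12) continue;  // parallel to triangle plane
        double inv = 1.0 / det;
        V3 tv = sub(o, va);
        double u = dot(tv, pvec) * inv;
        V3 qv = cross(tv, e1);
        double v = dot(d, qv) * inv;
        double t = dot(e2, qv) * inv;
        const double btol = 1e-9;
        if (t <= 0) continue;
        if (u < -btol || v < -btol || u + v > 1 + btol) continue;
        if (u < btol || v < btol || u + v > 1 - btol) { ambiguous = true; break; }
        crossings++;
      }
      if (!ambiguous) {
        out[i] = (crossings % 2) == 1;
        decided = true;
      }
    }
    if (!decided) out[i] = surf[i] <= eps;  // all directions grazed: fall back
  }
  return out;
}
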