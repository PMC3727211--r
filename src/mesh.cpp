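// Isosurface extraction by marching tetrahedra on the Freudenthal (Kuhn)
// 6-tetrahedra decomposition of each grid cube, and closest-point-on-mesh
// queries through a uniform spatial hash. The tetrahedral decomposition is
// translation-consistent across cubes, so the extracted surface is watertight
// by construction; vertices are deduplicated per grid edge.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector field, IntegerVector dims, double level,
                    NumericVector spacing, NumericVector origin) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *f = field.begin();
  auto F = [&](int i, int j, int k) {
    return f[(size_t)i + (size_t)n1 * (j + (size_t)n2 * k)];
  };
  auto nodeid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)n1 * ((int64_t)j + (int64_t)n2 * k);
  };
  // Freudenthal: 6 tets per cube, each a monotone path 000 -> 111.
  // Corner offsets indexed 0..7 as (dx, dy, dz) bits.
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {
    {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}};

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto edge_point = [&](int64_t idA, int64_t idB, double va, double vb,
                        int ia[3], int ib[3]) -> int {
    uint64_t key;
    if (idA < idB) key = ((uint64_t)idA << 32) | (uint64_t)idB;
    else           key = ((uint64_t)idB << 32) | (uint64_t)idA;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (!std::isfinite(t)) t = 0.5;
    if (t < 0) t = 0; if (t > 1) t = 1;
    double px = origin[0] + (ia[0] + t * (ib[0] - ia[0]) + 0.5) * spacing[0];
    double py = origin[1] + (ia[1] + t * (ib[1] - ia[1]) + 0.5) * spacing[1];
    double pz = origin[2] + (ia[2] + t * (ib[2] - ia[2]) + 0.5) * spacing[2];
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vertex[key] = id;
    return id;
  };

  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        double val[8]; int gi[8][3]; int64_t gid[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          gi[c][0] = i + corner[c][0]; gi[c][1] = j + corner[c][1]; gi[c][2] = k + corner[c][2];
          val[c] = F(gi[c][0], gi[c][1], gi[c][2]);
          gid[c] = nodeid(gi[c][0], gi[c][1], gi[c][2]);
          (val[c] > level ? anyin : anyout) = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int node[4] = {a, b, c, d};
          int inside[4], nin = 0;
          for (int q = 0; q < 4; ++q) { inside[q] = val[node[q]] > level; nin += inside[q]; }
          if (nin == 0 || nin == 4) continue;
          // collect crossing edges between inside/outside nodes
          int in_n[4], out_n[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) (inside[q] ? in_n[ni++] : out_n[no++]) = node[q];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in_n[0] : out_n[0];
            int others[3]; int m = 0;
            for (int q = 0; q < 4; ++q) if (node[q] != apex) others[m++] = node[q];
            int p0 = edge_point(gid[apex], gid[others[0]], val[apex], val[others[0]], gi[apex], gi[others[0]]);
            int p1 = edge_point(gid[apex], gid[others[1]], val[apex], val[others[1]], gi[apex], gi[others[1]]);
            int p2 = edge_point(gid[apex], gid[others[2]], val[apex], val[others[2]], gi[apex], gi[others[2]]);
            tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
          } else { // 2 in, 2 out -> quad split into two triangles
            int p00 = edge_point(gid[in_n[0]], gid[out_n[0]], val[in_n[0]], val[out_n[0]], gi[in_n[0]], gi[out_n[0]]);
            int p01 = edge_point(gid[in_n[0]], gid[out_n[1]], val[in_n[0]], val[out_n[1]], gi[in_n[0]], gi[out_n[1]]);
            int p10 = edge_point(gid[in_n[1]], gid[out_n[0]], val[in_n[1]], val[out_n[0]], gi[in_n[1]], gi[out_n[0]]);
            int p11 = edge_point(gid[in_n[1]], gid[out_n[1]], val[in_n[1]], val[out_n[1]], gi[in_n[1]], gi[out_n[1]]);
            tri.push_back(p00); tri.push_back(p01); tri.push_back(p11);
            tri.push_back(p00); tri.push_back(p11); tri.push_back(p10);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; ++q) { V(q, 0) = vx[q]; V(q, 1) = vy[q]; V(q, 2) = vz[q]; }
  IntegerMatrix Fc(nt, 3);
  for (int q = 0; q < nt; ++q) {
    Fc(q, 0) = tri[3 * q] + 1; Fc(q, 1) = tri[3 * q + 1] + 1; Fc(q, 2) = tri[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---- closest point on a triangle (Ericson, Real-Time Collision Detection) ----
static inline void closest_on_tri(const double *p, const double *a, const double *b,
                                  const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int q = 0; q < 3; ++q) { ab[q] = b[q] - a[q]; ac[q] = c[q] - a[q]; ap[q] = p[q] - a[q]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int q=0;q<3;++q) out[q]=a[q]; return; }
  double bp[3]; for (int q=0;q<3;++q) bp[q]=p[q]-b[q];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int q=0;q<3;++q) out[q]=b[q]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int q=0;q<3;++q) out[q] = a[q] + v*ab[q];
    return;
  }
  double cp[3]; for (int q=0;q<3;++q) cp[q]=p[q]-c[q];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int q=0;q<3;++q) out[q]=c[q]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int q=0;q<3;++q) out[q] = a[q] + w*ac[q];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int q=0;q<3;++q) out[q] = b[q] + w*(c[q]-b[q]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int q=0;q<3;++q) out[q] = a[q] + ab[q]*v + ac[q]*w;
}

// [[Rcpp::export(name = ".closest_on_mesh_cpp")]]
List closest_on_mesh_cpp(NumericMatrix query, NumericMatrix V, IntegerMatrix Fc) {
  const int nq = query.nrow(), nt = Fc.nrow();
  // uniform grid over triangle AABBs
  double lo[3], hi[3];
  for (int q = 0; q < 3; ++q) { lo[q] = R_PosInf; hi[q] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int q = 0; q < 3; ++q) {
      if (V(i, q) < lo[q]) lo[q] = V(i, q);
      if (V(i, q) > hi[q]) hi[q] = V(i, q);
    }
  double ext = 0.0;
  for (int q = 0; q < 3; ++q) ext = std::max(ext, hi[q] - lo[q]);
  int target_cells = std::max(8, (int)std::cbrt((double)nt));
  double h = std::max(ext / target_cells, 1e-9);
  int ng[3];
  for (int q = 0; q < 3; ++q) ng[q] = std::max(1, (int)std::floor((hi[q] - lo[q]) / h) + 1);
  auto cellof = [&](double x, int ax) {
    int c = (int)std::floor((x - lo[ax]) / h);
    if (c < 0) c = 0; if (c >= ng[ax]) c = ng[ax] - 1;
    return c;
  };
  std::vector<std::vector<int>> bucket((size_t)ng[0] * ng[1] * ng[2]);
  auto bidx = [&](int a, int b, int c) { return (size_t)a + (size_t)ng[0] * (b + (size_t)ng[1] * c); };
  for (int t = 0; t < nt; ++t) {
    int c0[3], c1[3];
    for (int q = 0; q < 3; ++q) {
      double tlo = R_PosInf, thi = R_NegInf;
      for (int m = 0; m < 3; ++m) {
        double v = V(Fc(t, m) - 1, q);
        if (v < tlo) tlo = v;
        if (v > thi) thi = v;
      }
      c0[q] = cellof(tlo, q); c1[q] = cellof(thi, q);
    }
    for (int c = c0[2]; c <= c1[2]; ++c)
      for (int b = c0[1]; b <= c1[1]; ++b)
        for (int a = c0[0]; a <= c1[0]; ++a)
          bucket[bidx(a, b, c)].push_back(t);
  }

  NumericMatrix out(nq, 3);
  NumericVector dist(nq);
  double ta[3], tb[3], tc[3], cp[3], p[3];
  for (int iq = 0; iq < nq; ++iq) {
    for (int q = 0; q < 3; ++q) p[q] = query(iq, q);
    int pc[3];
    for (int q = 0; q < 3; ++q) pc[q] = cellof(p[q], q);
    double best = R_PosInf; double bestp[3] = {0, 0, 0};
    int maxr = std::max(std::max(ng[0], ng[1]), ng[2]);
    for (int r = 0; r <= maxr; ++r) {
      // search shell at radius r
      bool any = false;
      int a0 = std::max(0, pc[0] - r), a1 = std::min(ng[0] - 1, pc[0] + r);
      int b0 = std::max(0, pc[1] - r), b1 = std::min(ng[1] - 1, pc[1] + r);
      int d0 = std::max(0, pc[2] - r), d1 = std::min(ng[2] - 1, pc[2] + r);
      for (int c = d0; c <= d1; ++c)
        for (int b = b0; b <= b1; ++b)
          for (int a = a0; a <= a1; ++a) {
            if (r > 0 && std::abs(a - pc[0]) != r && std::abs(b - pc[1]) != r && std::abs(c - pc[2]) != r)
              continue; // interior already searched
            const std::vector<int> &lst = bucket[bidx(a, b, c)];
            for (size_t m = 0; m < lst.size(); ++m) {
              any = true;
              int t = lst[m];
              for (int q = 0; q < 3; ++q) {
                ta[q] = V(Fc(t, 0) - 1, q); tb[q] = V(Fc(t, 1) - 1, q); tc[q] = V(Fc(t, 2) - 1, q);
              }
              closest_on_tri(p, ta, tb, tc, cp);
              double d = 0;
              for (int q = 0; q < 3; ++q) { double e = cp[q] - p[q]; d += e * e; }
              if (d < best) { best = d; for (int q = 0; q < 3; ++q) bestp[q] = cp[q]; }
            }
          }
      // safe stop: anything in farther shells is at least r*h away from the
      // query's cell boundary
      if (best < R_PosInf && std::sqrt(best) <= (double)r * h) break;
      (void)any;
    }
    for (int q = 0; q < 3; ++q) out(iq, q) = bestp[q];
    dist[iq] = std::sqrt(best);
  }
  return List::create(_["points"] = out, _["dist"] = dist);
}
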