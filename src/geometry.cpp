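// Geometry kernels: iso-surfacing, voxelization, point-mesh queries,
// binary morphology and connected components on 3D grids.
//
// Conventions: R arrays are column-major, voxel (i,j,k) lives at
// origin + c(i,j,k) * spacing (0-based indices, voxel centres).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <queue>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, ch. 5.1.5.
static void closest_on_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// ---------------------------------------------------------------------------
// Nearest point on a triangle mesh, with a uniform-grid acceleration
// structure.  Returns squared-distance, closest point and 1-based face index
// for every query point.
// [[Rcpp::export(name = ".cpp_mesh_nearest")]]
List cpp_mesh_nearest(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  const int nt = F.nrow(), np = P.nrow();
  if (nt == 0) stop("mesh has no triangles");
  // mesh bbox and mean triangle extent
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i, d) < lo[d]) lo[d] = V(i, d);
      if (V(i, d) > hi[d]) hi[d] = V(i, d);
    }
  double mean_ext = 0.0;
  for (int t = 0; t < nt; ++t) {
    double e = 0.0;
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int c = 0; c < 3; ++c) {
        double v = V(F(t, c) - 1, d);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      e = std::max(e, mx - mn);
    }
    mean_ext += e;
  }
  mean_ext /= nt;
  double diag = 0.0;
  for (int d = 0; d < 3; ++d) diag = std::max(diag, hi[d] - lo[d]);
  double h = std::max(mean_ext, diag / 96.0);
  if (!(h > 0)) h = 1.0;
  int ng[3];
  for (int d = 0; d < 3; ++d) {
    ng[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / h) + 1);
    ng[d] = std::min(ng[d], 96);
  }
  // cell size per axis so grid exactly covers bbox
  double cs[3];
  for (int d = 0; d < 3; ++d) cs[d] = std::max((hi[d] - lo[d]) / ng[d], 1e-12);
  std::vector<std::vector<int> > bins((size_t)ng[0] * ng[1] * ng[2]);
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cs[d]);
    return std::min(std::max(c, 0), ng[d] - 1);
  };
  for (int t = 0; t < nt; ++t) {
    int cmin[3], cmax[3];
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int c = 0; c < 3; ++c) {
        double v = V(F(t, c) - 1, d);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      cmin[d] = cell_of(mn, d);
      cmax[d] = cell_of(mx, d);
    }
    for (int k = cmin[2]; k <= cmax[2]; ++k)
      for (int j = cmin[1]; j <= cmax[1]; ++j)
        for (int i = cmin[0]; i <= cmax[0]; ++i)
          bins[i + (size_t)ng[0] * (j + (size_t)ng[1] * k)].push_back(t);
  }
  double hmin = std::min(cs[0], std::min(cs[1], cs[2]));
  // flat triangle coordinate cache
  std::vector<double> T9((size_t)nt * 9);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d)
        T9[(size_t)t * 9 + c * 3 + d] = V(F(t, c) - 1, d);
  // squared distance from a point to an axis-aligned cell box
  auto cell_lb2 = [&](const double* q, int i, int j, int k) {
    double b0[3] = {lo[0] + i * cs[0], lo[1] + j * cs[1], lo[2] + k * cs[2]};
    double b1[3] = {b0[0] + cs[0], b0[1] + cs[1], b0[2] + cs[2]};
    double s = 0.0;
    for (int d = 0; d < 3; ++d) {
      double dd = 0.0;
      if (q[d] < b0[d]) dd = b0[d] - q[d];
      else if (q[d] > b1[d]) dd = q[d] - b1[d];
      s += dd * dd;
    }
    return s;
  };

  NumericVector dist(np);
  NumericMatrix CP(np, 3);
  IntegerVector face(np);
  double q[3], cp[3];
  for (int ip = 0; ip < np; ++ip) {
    for (int d = 0; d < 3; ++d) q[d] = P(ip, d);
    int c0[3];
    double clampd2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      c0[d] = cell_of(q[d], d);
      double dd = 0.0;
      if (q[d] < lo[d]) dd = lo[d] - q[d];
      else if (q[d] > hi[d]) dd = q[d] - hi[d];
      clampd2 += dd * dd;
    }
    double clampd = std::sqrt(clampd2);
    double best = R_PosInf;
    int bestf = -1;
    double bestp[3] = {0, 0, 0};
    int maxR = std::max(ng[0], std::max(ng[1], ng[2]));
    for (int R = 0; R <= maxR; ++R) {
      double lb = (R - 1) * hmin - clampd;  // conservative ring lower bound
      if (lb > 0 && lb * lb > best) break;
      // iterate cells at Chebyshev distance R from c0
      int i0 = std::max(c0[0] - R, 0), i1 = std::min(c0[0] + R, ng[0] - 1);
      int j0 = std::max(c0[1] - R, 0), j1 = std::min(c0[1] + R, ng[1] - 1);
      int k0 = std::max(c0[2] - R, 0), k1 = std::min(c0[2] + R, ng[2] - 1);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            int cheb = std::max(std::abs(i - c0[0]),
                       std::max(std::abs(j - c0[1]), std::abs(k - c0[2])));
            if (cheb != R) continue;
            const std::vector<int>& b = bins[i + (size_t)ng[0] * (j + (size_t)ng[1] * k)];
            if (b.empty() || cell_lb2(q, i, j, k) > best) continue;
            for (size_t bi = 0; bi < b.size(); ++bi) {
              int t = b[bi];
              const double* tp = &T9[(size_t)t * 9];
              closest_on_triangle(q, tp, tp + 3, tp + 6, cp);
              double d2 = 0.0;
              for (int d = 0; d < 3; ++d) {
                double dd = cp[d] - q[d];
                d2 += dd * dd;
              }
              if (d2 < best) {
                best = d2;
                bestf = t;
                for (int d = 0; d < 3; ++d) bestp[d] = cp[d];
              }
            }
          }
    }
    dist[ip] = std::sqrt(best);
    face[ip] = bestf + 1;
    for (int d = 0; d < 3; ++d) CP(ip, d) = bestp[d];
  }
  return List::create(_["distance"] = dist, _["point"] = CP, _["face"] = face);
}

// ---------------------------------------------------------------------------
// Parity-based point-in-mesh (ray along +x), brute force over triangles.
// Rays are jittered off lattice planes to dodge exact vertex/edge hits.
// [[Rcpp::export(name = ".cpp_points_in_mesh")]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  const int nt = F.nrow(), np = P.nrow();
  LogicalVector inside(np);
  // precompute triangle vertex coords
  std::vector<double> tx(3 * nt), ty(3 * nt), tz(3 * nt);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) {
      tx[3 * t + c] = V(F(t, c) - 1, 0);
      ty[3 * t + c] = V(F(t, c) - 1, 1);
      tz[3 * t + c] = V(F(t, c) - 1, 2);
    }
  const double eps1 = 1.2345e-7, eps2 = 2.7182e-7;
  for (int ip = 0; ip < np; ++ip) {
    double px = P(ip, 0), py = P(ip, 1) + eps1, pz = P(ip, 2) + eps2;
    int cnt = 0;
    for (int t = 0; t < nt; ++t) {
      double y0 = ty[3 * t] - py, y1 = ty[3 * t + 1] - py, y2 = ty[3 * t + 2] - py;
      double z0 = tz[3 * t] - pz, z1 = tz[3 * t + 1] - pz, z2 = tz[3 * t + 2] - pz;
      // 2D barycentric of origin in projected triangle
      double d00 = y1 * z2 - y2 * z1;
      double d01 = y2 * z0 - y0 * z2;
      double d02 = y0 * z1 - y1 * z0;
      double area = d00 + d01 + d02;
      if (area == 0.0) continue;
      double b0 = d00 / area, b1 = d01 / area, b2 = d02 / area;
      if (b0 < 0 || b1 < 0 || b2 < 0) continue;
      double xhit = b0 * tx[3 * t] + b1 * tx[3 * t + 1] + b2 * tx[3 * t + 2];
      if (xhit > px) ++cnt;
    }
    inside[ip] = (cnt % 2) == 1;
  }
  return inside;
}

// ---------------------------------------------------------------------------
// Voxelize a closed mesh onto a grid: for every (y,z) lattice line cast one
// +x ray, collect crossings, and mark voxels in odd-parity intervals.
// Triangles are binned by their (y,z) bounding box for speed.
// [[Rcpp::export(name = ".cpp_voxelize_mesh")]]
LogicalVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double spacing,
                                IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nt = F.nrow();
  LogicalVector out((size_t)nx * ny * nz);
  const double eps1 = 1.2345e-7 * spacing, eps2 = 2.7182e-7 * spacing;
  // bin triangles over (j,k) ray lattice
  std::vector<std::vector<int> > bins((size_t)ny * nz);
  for (int t = 0; t < nt; ++t) {
    double ymn = R_PosInf, ymx = R_NegInf, zmn = R_PosInf, zmx = R_NegInf;
    for (int c = 0; c < 3; ++c) {
      double y = V(F(t, c) - 1, 1), z = V(F(t, c) - 1, 2);
      ymn = std::min(ymn, y); ymx = std::max(ymx, y);
      zmn = std::min(zmn, z); zmx = std::max(zmx, z);
    }
    int j0 = std::max(0, (int)std::ceil((ymn - eps1 - origin[1]) / spacing - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((ymx - eps1 - origin[1]) / spacing + 1e-9));
    int k0 = std::max(0, (int)std::ceil((zmn - eps2 - origin[2]) / spacing - 1e-9));
    int k1 = std::min(nz - 1, (int)std::floor((zmx - eps2 - origin[2]) / spacing + 1e-9));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bins[j + (size_t)ny * k].push_back(t);
  }
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    double rz = origin[2] + k * spacing + eps2;
    for (int j = 0; j < ny; ++j) {
      double ry = origin[1] + j * spacing + eps1;
      const std::vector<int>& b = bins[j + (size_t)ny * k];
      if (b.empty()) continue;
      xs.clear();
      for (size_t bi = 0; bi < b.size(); ++bi) {
        int t = b[bi];
        double y0 = V(F(t, 0) - 1, 1) - ry, y1 = V(F(t, 1) - 1, 1) - ry,
               y2 = V(F(t, 2) - 1, 1) - ry;
        double z0 = V(F(t, 0) - 1, 2) - rz, z1 = V(F(t, 1) - 1, 2) - rz,
               z2 = V(F(t, 2) - 1, 2) - rz;
        double d00 = y1 * z2 - y2 * z1;
        double d01 = y2 * z0 - y0 * z2;
        double d02 = y0 * z1 - y1 * z0;
        double area = d00 + d01 + d02;
        if (area == 0.0) continue;
        double b0 = d00 / area, b1 = d01 / area, b2 = d02 / area;
        if (b0 < 0 || b1 < 0 || b2 < 0) continue;
        xs.push_back(b0 * V(F(t, 0) - 1, 0) + b1 * V(F(t, 1) - 1, 0) +
                     b2 * V(F(t, 2) - 1, 0));
      }
      if (xs.size() < 2) continue;
      std::sort(xs.begin(), xs.end());
      for (size_t s = 0; s + 1 < xs.size(); s += 2) {
        int i0 = std::max(0, (int)std::ceil((xs[s] - origin[0]) / spacing));
        int i1 = std::min(nx - 1, (int)std::floor((xs[s + 1] - origin[0]) / spacing));
        for (int i = i0; i <= i1; ++i)
          out[i + (size_t)nx * (j + (size_t)ny * k)] = true;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over a scalar grid: returns a watertight, consistently
// outward-oriented triangulation of the iso-surface {value == iso}.
// Cube split into the six Kuhn tetrahedra around the 0-7 diagonal, which is
// face-consistent across neighbouring cubes.
// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector values, IntegerVector dim, double iso,
                       NumericVector origin, double spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto val = [&](int i, int j, int k) {
    return values[i + (size_t)nx * (j + (size_t)ny * k)];
  };
  auto nid = [&](int i, int j, int k) {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * (uint64_t)k);
  };
  static const int corner_off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {
    {0,1,5,7},{0,5,4,7},{0,4,6,7},{0,6,2,7},{0,2,3,7},{0,3,1,7}};

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> VX;
  std::vector<int> FX;
  edge_vertex.reserve(1 << 16);

  // edge vertex lookup/creation
  auto get_vertex = [&](uint64_t na, uint64_t nb, const double* pa,
                        const double* pb, double va, double vb) {
    uint64_t a = std::min(na, nb), b = std::max(na, nb);
    uint64_t packed = (a << 32) | b;  // node ids stay well below 2^32
    auto it = edge_vertex.find(packed);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    int id = (int)(VX.size() / 3);
    for (int d = 0; d < 3; ++d) VX.push_back(pa[d] + t * (pb[d] - pa[d]));
    edge_vertex.emplace(packed, id);
    return id;
  };

  double P[8][3];
  uint64_t N[8];
  double Vv[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // gather cube
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner_off[c][0], cj = j + corner_off[c][1],
              ck = k + corner_off[c][2];
          Vv[c] = val(ci, cj, ck);
          N[c] = nid(ci, cj, ck);
          P[c][0] = origin[0] + ci * spacing;
          P[c][1] = origin[1] + cj * spacing;
          P[c][2] = origin[2] + ck * spacing;
          if (Vv[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], nin = 0, nout = 0, in_list[4], out_list[4];
          for (int c = 0; c < 4; ++c) {
            ins[c] = Vv[idx[c]] > iso;
            if (ins[c]) in_list[nin++] = idx[c]; else out_list[nout++] = idx[c];
          }
          if (nin == 0 || nin == 4) continue;
          // centroids for orientation
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) cin[d] += P[in_list[c]][d] / nin;
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) cout[d] += P[out_list[c]][d] / nout;
          double dir[3] = {cout[0] - cin[0], cout[1] - cin[1], cout[2] - cin[2]};
          auto ev = [&](int a, int b) {
            return get_vertex(N[a], N[b], P[a], P[b], Vv[a], Vv[b]);
          };
          auto emit = [&](int v0, int v1, int v2) {
            // orient outward: normal . dir > 0
            const double* p0 = &VX[3 * v0];
            const double* p1 = &VX[3 * v1];
            const double* p2 = &VX[3 * v2];
            double e1[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
            double e2[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
            double nrm[3];
            cross3(e1, e2, nrm);
            if (dot3(nrm, dir) < 0) std::swap(v1, v2);
            FX.push_back(v0); FX.push_back(v1); FX.push_back(v2);
          };
          if (nin == 1) {
            int A = in_list[0];
            emit(ev(A, out_list[0]), ev(A, out_list[1]), ev(A, out_list[2]));
          } else if (nin == 3) {
            int D = out_list[0];
            emit(ev(in_list[0], D), ev(in_list[1], D), ev(in_list[2], D));
          } else {  // 2 in, 2 out -> quad
            int A = in_list[0], B = in_list[1], C = out_list[0], D = out_list[1];
            int eAC = ev(A, C), eAD = ev(A, D), eBC = ev(B, C), eBD = ev(B, D);
            emit(eAC, eAD, eBD);
            emit(eAC, eBD, eBC);
          }
        }
      }

  int nv = (int)(VX.size() / 3), nf = (int)(FX.size() / 3);
  NumericMatrix Vout(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) Vout(v, d) = VX[3 * v + d];
  IntegerMatrix Fout(nf, 3);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) Fout(f, c) = FX[3 * f + c] + 1;
  return List::create(_["vertices"] = Vout, _["triangles"] = Fout);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with zero padding.
// [[Rcpp::export(name = ".cpp_smooth3d")]]
NumericVector cpp_smooth3d(NumericVector values, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(values.begin(), values.end()), b(n, 0.0);
  const size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    std::fill(b.begin(), b.end(), 0.0);
    size_t st = strides[axis];
    int na = dims[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          int pos = (axis == 0) ? i : (axis == 1) ? j : k;
          double acc = 0.0;
          int o0 = std::max(-r, -pos), o1 = std::min(r, na - 1 - pos);
          for (int o = o0; o <= o1; ++o)
            acc += kern[o + r] * a[(size_t)((ptrdiff_t)idx + (ptrdiff_t)o * (ptrdiff_t)st)];
          b[idx] = acc;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Binary dilation by a Euclidean ball of radius r (in voxels); outside the
// array counts as background.
// [[Rcpp::export(name = ".cpp_binary_dilate")]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dim, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)std::floor(radius);
  std::vector<int> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          off.push_back(dx); off.push_back(dy); off.push_back(dz);
        }
  LogicalVector out((size_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[i + (size_t)nx * (j + (size_t)ny * k)]) continue;
        for (size_t o = 0; o < off.size(); o += 3) {
          int ii = i + off[o], jj = j + off[o + 1], kk = k + off[o + 2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[ii + (size_t)nx * (jj + (size_t)ny * kk)] = true;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 6-connected component labelling; label 0 = background.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;
  const int noff[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((size_t)nx * ny));
      for (int o = 0; o < 6; ++o) {
        int ii = i + noff[o][0], jj = j + noff[o][1], kk = k + noff[o][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
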