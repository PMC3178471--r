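#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Large-but-finite stand-in for +Inf inside the squared distance transform;
// keeps the lower-envelope intersection arithmetic finite.
static const double DT_BIG = 1e20;
static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// sample pitch h in mm.  f holds squared distances on entry, d on exit.
static void dt1d(const std::vector<double>& f, int n, double h,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s = 0.0;
    while (true) {
      double xp = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform of a labelled voxel grid:
// distance (mm) from each vessel voxel centre to the nearest background
// voxel centre; 0 on background.  Separable three-pass algorithm.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector vox, IntegerVector dims,
                      NumericVector spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (vox[i] > 0) ? DT_BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (fastest varying)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, n1, spacing[0], d, v, z);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, n2, spacing[1], d, v, z);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      R_xlen_t stride = (R_xlen_t)n1 * n2;
      for (int k = 0; k < n3; ++k) f[k] = out[base + stride * k];
      dt1d(f, n3, spacing[2], d, v, z);
      for (int k = 0; k < n3; ++k) out[base + stride * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (vox[i] > 0) ? std::sqrt(out[i]) : 0.0;
  return out;
}

// Dijkstra shortest path on the 26-connected voxel graph restricted to
// vessel voxels.  Edge cost = physical step length / (1 + dmap[target]),
// drawing paths toward the lumen centre.  start/end are 1-based linear
// indices; the returned path is 1-based, ordered start -> end.
// [[Rcpp::export]]
List cpp_dijkstra(IntegerVector vox, IntegerVector dims,
                  NumericVector spacing, NumericVector dmap,
                  int start, int end) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  int s = start - 1, e = end - 1;

  // precompute 26-neighbour offsets and physical step lengths
  std::vector<int> di, dj, dk;
  std::vector<double> step;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        di.push_back(a);
        dj.push_back(b);
        dk.push_back(c);
        double sx = a * spacing[0], sy = b * spacing[1], sz = c * spacing[2];
        step.push_back(std::sqrt(sx * sx + sy * sy + sz * sz));
      }

  std::vector<double> dist(n, INF);
  std::vector<int> prev(n, -1);
  std::vector<char> done(n, 0);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  dist[s] = 0.0;
  pq.push(QN(0.0, s));

  while (!pq.empty()) {
    QN top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == e) break;
    int ku = u / (n1 * n2);
    int rem = u - ku * n1 * n2;
    int ju = rem / n1;
    int iu = rem - ju * n1;
    for (size_t m = 0; m < di.size(); ++m) {
      int iv = iu + di[m], jv = ju + dj[m], kv = ku + dk[m];
      if (iv < 0 || iv >= n1 || jv < 0 || jv >= n2 || kv < 0 || kv >= n3)
        continue;
      R_xlen_t vdx = iv + (R_xlen_t)n1 * (jv + (R_xlen_t)n2 * kv);
      if (vox[vdx] <= 0 || done[vdx]) continue;
      double w = step[m] / (1.0 + dmap[vdx]);
      double nd = top.first + w;
      if (nd < dist[vdx]) {
        dist[vdx] = nd;
        prev[vdx] = u;
        pq.push(QN(nd, (int)vdx));
      }
    }
  }

  if (!done[e] && s != e)
    return List::create(Named("reachable") = false);

  std::vector<int> path;
  for (int u = e; u != -1; u = prev[u]) {
    path.push_back(u + 1);
    if (u == s) break;
  }
  std::reverse(path.begin(), path.end());
  return List::create(Named("reachable") = true,
                      Named("path") = wrap(path),
                      Named("cost") = dist[e]);
}

// Voxelize a union of capsule segments (tube pieces with linearly
// interpolated radius).  A voxel is labelled iff its centre lies within
// the local radius of some segment; competing labels resolved by the
// most interior claim (smallest distance - radius).
// segs columns: x1 y1 z1 x2 y2 z2 r1 r2 label
// [[Rcpp::export]]
IntegerVector cpp_voxelize(IntegerVector dims, NumericVector spacing,
                           NumericVector origin, NumericMatrix segs) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<double> best(n, INF);

  for (int srow = 0; srow < segs.nrow(); ++srow) {
    double p1x = segs(srow, 0), p1y = segs(srow, 1), p1z = segs(srow, 2);
    double p2x = segs(srow, 3), p2y = segs(srow, 4), p2z = segs(srow, 5);
    double r1 = segs(srow, 6), r2 = segs(srow, 7);
    int label = (int)segs(srow, 8);
    double rmax = std::max(r1, r2);
    double dx = p2x - p1x, dy = p2y - p1y, dz = p2z - p1z;
    double len2 = dx * dx + dy * dy + dz * dz;

    double lox = std::min(p1x, p2x) - rmax, hix = std::max(p1x, p2x) + rmax;
    double loy = std::min(p1y, p2y) - rmax, hiy = std::max(p1y, p2y) + rmax;
    double loz = std::min(p1z, p2z) - rmax, hiz = std::max(p1z, p2z) + rmax;
    int ilo = std::max(0, (int)std::floor((lox - origin[0]) / spacing[0]));
    int ihi = std::min(n1 - 1, (int)std::ceil((hix - origin[0]) / spacing[0]));
    int jlo = std::max(0, (int)std::floor((loy - origin[1]) / spacing[1]));
    int jhi = std::min(n2 - 1, (int)std::ceil((hiy - origin[1]) / spacing[1]));
    int klo = std::max(0, (int)std::floor((loz - origin[2]) / spacing[2]));
    int khi = std::min(n3 - 1, (int)std::ceil((hiz - origin[2]) / spacing[2]));

    for (int k = klo; k <= khi; ++k) {
      double cz = origin[2] + k * spacing[2];
      for (int j = jlo; j <= jhi; ++j) {
        double cy = origin[1] + j * spacing[1];
        for (int i = ilo; i <= ihi; ++i) {
          double cx = origin[0] + i * spacing[0];
          double t = 0.0;
          if (len2 > 0.0) {
            t = ((cx - p1x) * dx + (cy - p1y) * dy + (cz - p1z) * dz) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double qx = p1x + t * dx - cx;
          double qy = p1y + t * dy - cy;
          double qz = p1z + t * dz - cz;
          double d = std::sqrt(qx * qx + qy * qy + qz * qz);
          double r = r1 + t * (r2 - r1);
          if (d <= r) {
            R_xlen_t idx = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
            double score = d - r;
            if (score < best[idx]) {
              best[idx] = score;
              lab[idx] = label;
            }
          }
        }
      }
    }
  }
  return lab;
}

// Trilinear interpolation of a scalar voxel field at world-coordinate
// points (mm).  Points outside the grid hull evaluate to 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double gx = (pts(p, 0) - origin[0]) / spacing[0];
    double gy = (pts(p, 1) - origin[1]) / spacing[1];
    double gz = (pts(p, 2) - origin[2]) / spacing[2];
    if (gx < 0 || gx > n1 - 1 || gy < 0 || gy > n2 - 1 ||
        gz < 0 || gz > n3 - 1) {
      out[p] = 0.0;
      continue;
    }
    int i0 = std::min((int)std::floor(gx), n1 - 2);
    int j0 = std::min((int)std::floor(gy), n2 - 2);
    int k0 = std::min((int)std::floor(gz), n3 - 2);
    if (n1 == 1) i0 = 0;
    if (n2 == 1) j0 = 0;
    if (n3 == 1) k0 = 0;
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      int k = std::min(k0 + dk, n3 - 1);
      double wk = dk ? fz : 1.0 - fz;
      if (wk == 0.0) continue;
      for (int dj = 0; dj <= 1; ++dj) {
        int j = std::min(j0 + dj, n2 - 1);
        double wj = dj ? fy : 1.0 - fy;
        if (wj == 0.0) continue;
        for (int di = 0; di <= 1; ++di) {
          int i = std::min(i0 + di, n1 - 1);
          double wi = di ? fx : 1.0 - fx;
          if (wi == 0.0) continue;
          acc += wi * wj * wk *
                 values[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}
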