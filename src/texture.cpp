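#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-voxel texture kernels. Conventions shared with the R-level naive
// oracles: GLCM and orientation windows are clipped to the volume bounds
// (no padding); gray-filter windows and convolutions use replicate
// (clamped-index) padding.

static const double LOG2 = std::log(2.0);

// Sparse accumulator for one co-occurrence matrix: dense storage with a
// touched-cell list so per-voxel resets cost O(pairs), not O(L^2).
struct GlcmWork {
  std::vector<double> P;
  std::vector<int> touched;
  std::vector<double> px, py;
  std::vector<int> nzx, nzy;
  void init(int L) {
    P.assign((size_t)L * L, 0.0);
    px.assign(L, 0.0);
    py.assign(L, 0.0);
    touched.clear();
    nzx.clear();
    nzy.clear();
  }
  void reset(int L) {
    for (int c : touched) P[c] = 0.0;
    for (int i : nzx) px[i] = 0.0;
    for (int j : nzy) py[j] = 0.0;
    touched.clear();
    nzx.clear();
    nzy.clear();
  }
  inline void add(int i, int j, int L) {
    size_t c = (size_t)i + (size_t)L * j;
    if (P[c] == 0.0) touched.push_back((int)c);
    P[c] += 1.0;
  }
};

// 13 classic Haralick statistics from the sparse accumulator (already
// normalized to sum 1). Degenerate denominators map to 0 so no non-finite
// values escape.
static void haralick13_sparse(GlcmWork& w, int L, double* out) {
  for (int i = 0; i < L; ++i) w.px[i] = 0.0;
  for (int j = 0; j < L; ++j) w.py[j] = 0.0;

  std::vector<double> pxy(2 * L - 1, 0.0), pxmy(L, 0.0);
  double energy = 0, contrast = 0, idm = 0, entropy = 0, corr_num = 0;
  for (int c : w.touched) {
    double p = w.P[c];
    if (p <= 0) continue;
    int i = c % L, j = c / L;
    w.px[i] += p; w.py[j] += p;
    pxy[i + j] += p;
    pxmy[std::abs(i - j)] += p;
    energy += p * p;
    contrast += (double)(i - j) * (i - j) * p;
    idm += p / (1.0 + (double)(i - j) * (i - j));
    entropy -= p * std::log(p) / LOG2;
    corr_num += (double)(i + 1) * (j + 1) * p;
  }
  w.nzx.clear(); w.nzy.clear();
  for (int i = 0; i < L; ++i) if (w.px[i] > 0) w.nzx.push_back(i);
  for (int j = 0; j < L; ++j) if (w.py[j] > 0) w.nzy.push_back(j);

  double mux = 0, muy = 0;
  for (int i : w.nzx) mux += (i + 1) * w.px[i];
  for (int j : w.nzy) muy += (j + 1) * w.py[j];
  double sx2 = 0, sy2 = 0;
  for (int i : w.nzx) sx2 += (i + 1 - mux) * (i + 1 - mux) * w.px[i];
  for (int j : w.nzy) sy2 += (j + 1 - muy) * (j + 1 - muy) * w.py[j];
  double correlation = 0;
  if (sx2 > 0 && sy2 > 0) correlation = (corr_num - mux * muy) / std::sqrt(sx2 * sy2);
  double variance = sx2;  // symmetric accumulation: x and y marginals equal

  double sumavg = 0, sument = 0;
  for (int k = 0; k < 2 * L - 1; ++k) {
    if (pxy[k] > 0) {
      sumavg += (k + 2) * pxy[k];
      sument -= pxy[k] * std::log(pxy[k]) / LOG2;
    }
  }
  double sumvar = 0;
  for (int k = 0; k < 2 * L - 1; ++k)
    if (pxy[k] > 0) sumvar += ((k + 2) - sumavg) * ((k + 2) - sumavg) * pxy[k];

  double dmu = 0, dvar = 0, dent = 0;
  for (int k = 0; k < L; ++k) if (pxmy[k] > 0) dmu += k * pxmy[k];
  for (int k = 0; k < L; ++k) {
    if (pxmy[k] > 0) {
      dvar += (k - dmu) * (k - dmu) * pxmy[k];
      dent -= pxmy[k] * std::log(pxmy[k]) / LOG2;
    }
  }

  double hx = 0, hy = 0, hxy1 = 0, hxy2 = 0;
  for (int i : w.nzx) hx -= w.px[i] * std::log(w.px[i]) / LOG2;
  for (int j : w.nzy) hy -= w.py[j] * std::log(w.py[j]) / LOG2;
  for (int i : w.nzx) {
    for (int j : w.nzy) {
      double pp = w.px[i] * w.py[j];
      double lg = std::log(pp) / LOG2;
      hxy2 -= pp * lg;
      double p = w.P[(size_t)i + (size_t)L * j];
      if (p > 0) hxy1 -= p * lg;
    }
  }
  double imc1 = 0;
  double hmax = std::max(hx, hy);
  if (hmax > 0) imc1 = (entropy - hxy1) / hmax;
  double arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  double imc2 = arg > 0 ? std::sqrt(arg) : 0.0;

  out[0] = energy;   out[1] = contrast; out[2] = correlation; out[3] = variance;
  out[4] = idm;      out[5] = sumavg;   out[6] = sumvar;      out[7] = sument;
  out[8] = entropy;  out[9] = dvar;     out[10] = dent;       out[11] = imc1;
  out[12] = imc2;
}

static void neutral_stats(double* s, int own_label) {
  for (int k = 0; k < 13; ++k) s[k] = 0.0;
  s[0] = 1.0; s[4] = 1.0; s[5] = 2.0 * own_label;
}

// [[Rcpp::export]]
NumericVector cpp_haralick_stats(NumericMatrix glcm) {
  int L = glcm.nrow();
  GlcmWork w;
  w.init(L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      double p = glcm(i, j);
      if (p > 0) {
        w.P[(size_t)i + (size_t)L * j] = p;
        w.touched.push_back(i + L * j);
      }
    }
  NumericVector out(13);
  haralick13_sparse(w, L, REAL(out));
  return out;
}

// Sliding-window GLCM + 13 Haralick statistics at each evaluation voxel,
// simultaneously for several gray-level quantizations (one column of
// `labels_multi` per quantization; 0 = ignore). The window pair geometry is
// enumerated once per voxel and reused across quantizations. Windows are
// clipped at the volume bounds; a window with no valid pair yields the
// neutral constant-patch statistics. Output: nev x (13 * n_quant), the 13
// statistics of quantization q in columns 13*q .. 13*q+12.
// [[Rcpp::export]]
NumericMatrix cpp_haralick_maps_multi(IntegerMatrix labels_multi, IntegerVector dims,
                                      IntegerVector eval_idx, IntegerVector radii,
                                      IntegerVector levels_vec, IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rx = radii[0], ry = radii[1], rz = radii[2];
  int nev = eval_idx.size(), noff = offsets.nrow(), nq = levels_vec.size();
  int Lmax = 0;
  for (int q = 0; q < nq; ++q) Lmax = std::max(Lmax, (int)levels_vec[q]);
  NumericMatrix out(nev, 13 * nq);
  std::vector<GlcmWork> work(nq);
  for (int q = 0; q < nq; ++q) work[q].init(levels_vec[q]);
  std::vector<int> pa, pb;           // pair endpoints (linear indices)
  std::vector<int> rel_a, rel_b;     // precomputed interior-window pair offsets
  pa.reserve(8192); pb.reserve(8192);

  for (int e = 0; e < nev; ++e) {
    int lin = eval_idx[e];
    int cx = lin % nx, cy = (lin / nx) % ny, cz = lin / (nx * ny);
    int x0 = std::max(0, cx - rx), x1 = std::min(nx - 1, cx + rx);
    int y0 = std::max(0, cy - ry), y1 = std::min(ny - 1, cy + ry);
    int z0 = std::max(0, cz - rz), z1 = std::min(nz - 1, cz + rz);
    bool interior = (cx >= rx && cx + rx < nx && cy >= ry && cy + ry < ny &&
                     cz >= rz && cz + rz < nz);
    int npair;
    if (interior) {
      // window fully inside the volume: reuse the precomputed relative
      // pair offsets (computed on first use)
      if (rel_a.empty()) {
        for (int dz = -rz; dz <= rz; ++dz)
          for (int dy = -ry; dy <= ry; ++dy)
            for (int dx = -rx; dx <= rx; ++dx)
              for (int o = 0; o < noff; ++o) {
                int qx = dx + offsets(o, 0), qy = dy + offsets(o, 1), qz = dz + offsets(o, 2);
                if (qx < -rx || qx > rx || qy < -ry || qy > ry || qz < -rz || qz > rz)
                  continue;
                rel_a.push_back(dx + nx * (dy + ny * dz));
                rel_b.push_back(qx + nx * (qy + ny * qz));
              }
      }
      npair = (int)rel_a.size();
      pa.resize(npair); pb.resize(npair);
      for (int t = 0; t < npair; ++t) {
        pa[t] = lin + rel_a[t];
        pb[t] = lin + rel_b[t];
      }
    } else {
      pa.clear(); pb.clear();
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            int p = x + nx * (y + ny * z);
            for (int o = 0; o < noff; ++o) {
              int qx = x + offsets(o, 0), qy = y + offsets(o, 1), qz = z + offsets(o, 2);
              if (qx < x0 || qx > x1 || qy < y0 || qy > y1 || qz < z0 || qz > z1)
                continue;
              pa.push_back(p);
              pb.push_back(qx + nx * (qy + ny * qz));
            }
          }
      npair = (int)pa.size();
    }
    for (int q = 0; q < nq; ++q) {
      int L = levels_vec[q];
      const int* lab = &labels_multi(0, q);
      GlcmWork& w = work[q];
      w.reset(L);
      double total = 0;
      for (int t = 0; t < npair; ++t) {
        int la = lab[pa[t]], lb = lab[pb[t]];
        if (la <= 0 || lb <= 0) continue;
        w.add(la - 1, lb - 1, L);
        w.add(lb - 1, la - 1, L);
        total += 2.0;
      }
      double stats[13];
      if (total <= 0) {
        neutral_stats(stats, lab[lin]);
      } else {
        for (int c : w.touched) w.P[c] /= total;
        haralick13_sparse(w, L, stats);
      }
      for (int s = 0; s < 13; ++s) out(e, 13 * q + s) = stats[s];
    }
  }
  return out;
}

// Single-quantization wrapper (used by the CoLlAGe orientation maps).
// [[Rcpp::export]]
NumericMatrix cpp_haralick_maps(IntegerVector labels, IntegerVector dims,
                                IntegerVector eval_idx, IntegerVector radii,
                                int levels, IntegerMatrix offsets) {
  IntegerMatrix lm(labels.size(), 1);
  std::copy(labels.begin(), labels.end(), lm.column(0).begin());
  return cpp_haralick_maps_multi(lm, dims, eval_idx, radii,
                                 IntegerVector::create(levels), offsets);
}

// Sliding-window mean / median / sample sd / range with replicate padding
// (clamped indices, so edge voxels are counted multiply as in replicate
// padding).
// [[Rcpp::export]]
NumericMatrix cpp_window_stats(NumericVector vol, IntegerVector dims,
                               IntegerVector eval_idx, IntegerVector radii) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rx = radii[0], ry = radii[1], rz = radii[2];
  int nev = eval_idx.size();
  int wn = (2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1);
  NumericMatrix out(nev, 4);
  std::vector<double> w(wn);
  const double* v = REAL(vol);

  for (int e = 0; e < nev; ++e) {
    int lin = eval_idx[e];
    int cx = lin % nx, cy = (lin / nx) % ny, cz = lin / (nx * ny);
    int k = 0;
    double sum = 0, mn = R_PosInf, mx = R_NegInf;
    for (int dz = -rz; dz <= rz; ++dz)
      for (int dy = -ry; dy <= ry; ++dy)
        for (int dx = -rx; dx <= rx; ++dx) {
          int x = std::min(std::max(cx + dx, 0), nx - 1);
          int y = std::min(std::max(cy + dy, 0), ny - 1);
          int z = std::min(std::max(cz + dz, 0), nz - 1);
          double val = v[x + nx * (y + ny * z)];
          w[k++] = val;
          sum += val;
          if (val < mn) mn = val;
          if (val > mx) mx = val;
        }
    double mean = sum / wn;
    double ss = 0;
    for (int i = 0; i < wn; ++i) ss += (w[i] - mean) * (w[i] - mean);
    double sd = wn > 1 ? std::sqrt(ss / (wn - 1)) : 0.0;
    std::vector<double> ws(w);
    std::nth_element(ws.begin(), ws.begin() + wn / 2, ws.end());
    double med = ws[wn / 2];
    if (wn % 2 == 0) {
      std::nth_element(ws.begin(), ws.begin() + wn / 2 - 1, ws.end());
      med = 0.5 * (med + ws[wn / 2 - 1]);
    }
    out(e, 0) = mean; out(e, 1) = med; out(e, 2) = sd; out(e, 3) = mx - mn;
  }
  return out;
}

// 1D correlation along one axis (1-based axis) with an odd-length kernel,
// replicate padding: out[i] = sum_o k[o + r] * in[i + o].
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int len = kernel.size(), r = (len - 1) / 2;
  int n_ax = dims[axis - 1];
  NumericVector out(vol.size());
  const double* v = REAL(vol);
  double* o = REAL(out);
  const double* k = REAL(kernel);
  int stride = axis == 1 ? 1 : (axis == 2 ? nx : nx * ny);

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int pos = axis == 1 ? x : (axis == 2 ? y : z);
        int base = x + nx * (y + ny * z);
        double acc = 0;
        for (int t = 0; t < len; ++t) {
          int p = pos + t - r;
          if (p < 0) p = 0;
          if (p >= n_ax) p = n_ax - 1;
          acc += k[t] * v[base + (p - pos) * stride];
        }
        o[base] = acc;
      }
  return out;
}

// Dominant local gradient orientation: principal eigenvector of the
// windowed structure tensor (sum of gradient outer products), window
// clipped to bounds. Rows with negligible gradient energy return (0,0,0)
// so callers can assign the reserved orientation bin.
// [[Rcpp::export]]
NumericMatrix cpp_dominant_orientation(NumericVector gx, NumericVector gy,
                                       NumericVector gz, IntegerVector dims,
                                       IntegerVector eval_idx, IntegerVector radii) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rx = radii[0], ry = radii[1], rz = radii[2];
  int nev = eval_idx.size();
  NumericMatrix out(nev, 3);
  const double *px = REAL(gx), *py = REAL(gy), *pz = REAL(gz);

  for (int e = 0; e < nev; ++e) {
    int lin = eval_idx[e];
    int cx = lin % nx, cy = (lin / nx) % ny, cz = lin / (nx * ny);
    int x0 = std::max(0, cx - rx), x1 = std::min(nx - 1, cx + rx);
    int y0 = std::max(0, cy - ry), y1 = std::min(ny - 1, cy + ry);
    int z0 = std::max(0, cz - rz), z1 = std::min(nz - 1, cz + rz);
    double a = 0, b = 0, c = 0, d = 0, f = 0, g = 0;  // tensor xx,yy,zz,xy,xz,yz
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          int q = x + nx * (y + ny * z);
          a += px[q] * px[q]; b += py[q] * py[q]; c += pz[q] * pz[q];
          d += px[q] * py[q]; f += px[q] * pz[q]; g += py[q] * pz[q];
        }
    double tr = a + b + c;
    if (tr < 1e-24) { out(e, 0) = out(e, 1) = out(e, 2) = 0.0; continue; }
    // power iteration, deterministic start
    double vx = 1.0, vy = 1.0, vz = 1.0;
    for (int it = 0; it < 30; ++it) {
      double ux = a * vx + d * vy + f * vz;
      double uy = d * vx + b * vy + g * vz;
      double uz = f * vx + g * vy + c * vz;
      double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (nrm < 1e-30) break;
      vx = ux / nrm; vy = uy / nrm; vz = uz / nrm;
    }
    out(e, 0) = vx; out(e, 1) = vy; out(e, 2) = vz;
  }
  return out;
}

struct MiWork {
  std::vector<double> joint, mx, my;
};

static void conv_axis_buf(const double* in, double* out, const int* d,
                          const double* k, int len, int axis) {
  int nx = d[0], ny = d[1], nz = d[2];
  int r = (len - 1) / 2;
  int n_ax = d[axis];
  int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int pos = axis == 0 ? x : (axis == 1 ? y : z);
        int base = x + nx * (y + ny * z);
        double acc = 0;
        for (int t = 0; t < len; ++t) {
          int p = pos + t - r;
          if (p < 0) p = 0;
          if (p >= n_ax) p = n_ax - 1;
          acc += k[t] * in[base + (p - pos) * stride];
        }
        out[base] = acc;
      }
}

// Full Laws texture-energy bank: separable correlation with all outer
// products of the five length-5 kernels, replicate padding, absolute
// response. Column order: x-kernel outermost, then y, then z (2D omits the
// z stage). Kernel order L5, E5, S5, W5, R5.
// [[Rcpp::export]]
NumericMatrix cpp_laws_maps(NumericVector vol, IntegerVector dims, bool mode3d) {
  static const double K[5][5] = {
    {1, 4, 6, 4, 1}, {-1, -2, 0, 2, 1}, {-1, 0, 2, 0, -1},
    {-1, 2, 0, -2, 1}, {1, -4, 6, -4, 1}
  };
  int d[3] = {dims[0], dims[1], dims[2]};
  size_t V = (size_t)d[0] * d[1] * d[2];
  int nmaps = mode3d ? 125 : 25;
  NumericMatrix out((int)V, nmaps);
  std::vector<double> bx(V), bxy(V), bxyz(V);
  int col = 0;
  for (int ix = 0; ix < 5; ++ix) {
    conv_axis_buf(REAL(vol), bx.data(), d, K[ix], 5, 0);
    for (int iy = 0; iy < 5; ++iy) {
      conv_axis_buf(bx.data(), bxy.data(), d, K[iy], 5, 1);
      if (!mode3d) {
        double* o = &out(0, col++);
        for (size_t v = 0; v < V; ++v) o[v] = std::fabs(bxy[v]);
      } else {
        for (int iz = 0; iz < 5; ++iz) {
          conv_axis_buf(bxy.data(), bxyz.data(), d, K[iz], 5, 2);
          double* o = &out(0, col++);
          for (size_t v = 0; v < V; ++v) o[v] = std::fabs(bxyz[v]);
        }
      }
    }
  }
  return out;
}

// Greedy redundancy elimination on an absolute correlation matrix:
// repeatedly take the pair with the largest |rho| >= threshold (ties:
// smallest row, then smallest column) and drop the member with the larger
// mean |rho| to all other remaining features (ties: the later column).
// Returns a logical keep vector.
// [[Rcpp::export]]
LogicalVector cpp_redundancy_greedy(NumericMatrix rho, double threshold) {
  int p = rho.nrow();
  std::vector<bool> alive(p, true);
  std::vector<double> rowsum(p, 0.0);       // sum |rho| to all other alive
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (j != i) rowsum[i] += rho(i, j);
  int n_alive = p;

  // rowmax[i]: max |rho(i, j)| over alive j > i, with its argmax
  std::vector<double> rowmax(p, -1.0);
  std::vector<int> rowarg(p, -1);
  auto recompute_row = [&](int i) {
    rowmax[i] = -1.0; rowarg[i] = -1;
    for (int j = i + 1; j < p; ++j)
      if (alive[j] && rho(i, j) > rowmax[i]) { rowmax[i] = rho(i, j); rowarg[i] = j; }
  };
  for (int i = 0; i < p; ++i) recompute_row(i);

  while (n_alive > 1) {
    int bi = -1; double best = -1.0;
    for (int i = 0; i < p; ++i)
      if (alive[i] && rowmax[i] > best) { best = rowmax[i]; bi = i; }
    if (best < threshold) break;
    int bj = rowarg[bi];
    double mean_i = rowsum[bi] / (n_alive - 1);
    double mean_j = rowsum[bj] / (n_alive - 1);
    int d = (mean_i > mean_j) ? bi : bj;     // tie -> later column (bj > bi)
    alive[d] = false;
    --n_alive;
    for (int i = 0; i < p; ++i)
      if (alive[i]) rowsum[i] -= rho(i, d);
    for (int i = 0; i < d; ++i)
      if (alive[i] && rowarg[i] == d) recompute_row(i);
    rowmax[d] = -1.0;
  }
  LogicalVector keep(p);
  for (int i = 0; i < p; ++i) keep[i] = alive[i];
  return keep;
}

static double mutual_info(const int* x, const int* y, const int* rows, int n,
                          int bx, int by, MiWork& w) {
  std::fill(w.joint.begin(), w.joint.begin() + bx * by, 0.0);
  std::fill(w.mx.begin(), w.mx.begin() + bx, 0.0);
  std::fill(w.my.begin(), w.my.begin() + by, 0.0);
  for (int i = 0; i < n; ++i) {
    int r = rows[i];
    w.joint[(x[r] - 1) + bx * (y[r] - 1)] += 1.0;
  }
  for (int j = 0; j < by; ++j)
    for (int i = 0; i < bx; ++i) {
      double p = w.joint[i + bx * j];
      w.mx[i] += p; w.my[j] += p;
    }
  double mi = 0;
  for (int j = 0; j < by; ++j)
    for (int i = 0; i < bx; ++i) {
      double p = w.joint[i + bx * j];
      if (p <= 0) continue;
      mi += (p / n) * std::log(p * n / (w.mx[i] * w.my[j]));
    }
  return mi;
}

// Greedy mRMR (MID difference form) on pre-binned features. bins: n x p
// integer matrix with values 1..n_bins; ybin: 1..n_bins_y; rows: 1-based
// row subset. Returns 1-based column order of length n_select.
// [[Rcpp::export]]
IntegerVector cpp_mrmr_rank(IntegerMatrix bins, IntegerVector ybin,
                            IntegerVector rows, int n_select,
                            int n_bins, int n_bins_y) {
  int p = bins.ncol();
  int n = rows.size();
  std::vector<int> r0(n);
  for (int i = 0; i < n; ++i) r0[i] = rows[i] - 1;
  MiWork w;
  int bmax = std::max(n_bins, n_bins_y);
  w.joint.assign((size_t)n_bins * bmax, 0.0);
  w.mx.assign(bmax, 0.0);
  w.my.assign(bmax, 0.0);

  std::vector<double> relevance(p);
  for (int j = 0; j < p; ++j)
    relevance[j] = mutual_info(&bins(0, j), &ybin[0], r0.data(), n, n_bins, n_bins_y, w);

  std::vector<bool> used(p, false);
  std::vector<double> red_sum(p, 0.0);
  IntegerVector sel(n_select);
  for (int s = 0; s < n_select; ++s) {
    int best = -1;
    double best_score = -1e300;
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      double score = relevance[j] - (s > 0 ? red_sum[j] / s : 0.0);
      if (score > best_score + 1e-12) { best_score = score; best = j; }
    }
    used[best] = true;
    sel[s] = best + 1;
    if (s + 1 < n_select) {
      for (int j = 0; j < p; ++j) {
        if (used[j]) continue;
        red_sum[j] += mutual_info(&bins(0, j), &bins(0, best), r0.data(), n,
                                  n_bins, n_bins, w);
      }
    }
  }
  return sel;
}
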