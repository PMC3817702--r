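// Scoring kernels for the toy-crystal backend: Gaussian overlap of rigid
// placements against symmetry-expanded ground truth, greedy truth matching,
// clash counting, translation-grid scanning and deterministic bin-keyed
// score noise.  All heavy loops of the mock likelihood live here.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline void matvec3(const double *M, const double *x, double *y) {
  // M column-major 3x3
  y[0] = M[0] * x[0] + M[3] * x[1] + M[6] * x[2];
  y[1] = M[1] * x[0] + M[4] * x[1] + M[7] * x[2];
  y[2] = M[2] * x[0] + M[5] * x[1] + M[8] * x[2];
}

// deterministic hash -> standard normal (splitmix64 + inverse CDF)
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static double hashNormal(const std::vector<int64_t> &key) {
  uint64_t h = 0x51ab2ecd9352fe83ULL;
  for (size_t i = 0; i < key.size(); ++i)
    h = splitmix64(h ^ (uint64_t)key[i]);
  double u = ((h >> 11) + 0.5) / 9007199254740992.0; // 53-bit uniform in (0,1)
  return R::qnorm(u, 0.0, 1.0, 1, 0);
}

// rotation matrix (column-major, 9 doubles) -> canonical-sign quaternion
static void rotToQuat(const double *R, double *q) {
  double tr = R[0] + R[4] + R[8];
  double w, x, y, z;
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    w = 0.25 * s; x = (R[5] - R[7]) / s; y = (R[6] - R[2]) / s; z = (R[1] - R[3]) / s;
  } else if (R[0] > R[4] && R[0] > R[8]) {
    double s = std::sqrt(1.0 + R[0] - R[4] - R[8]) * 2.0;
    w = (R[5] - R[7]) / s; x = 0.25 * s; y = (R[3] + R[1]) / s; z = (R[6] + R[2]) / s;
  } else if (R[4] > R[8]) {
    double s = std::sqrt(1.0 + R[4] - R[0] - R[8]) * 2.0;
    w = (R[6] - R[2]) / s; x = (R[3] + R[1]) / s; y = 0.25 * s; z = (R[5] + R[7]) / s;
  } else {
    double s = std::sqrt(1.0 + R[8] - R[0] - R[4]) * 2.0;
    w = (R[1] - R[3]) / s; x = (R[6] + R[2]) / s; y = (R[5] + R[7]) / s; z = 0.25 * s;
  }
  q[0] = w; q[1] = x; q[2] = y; q[3] = z;
  for (int i = 0; i < 4; ++i) {
    if (std::fabs(q[i]) > 1e-9) {
      if (q[i] < 0) { q[0] = -q[0]; q[1] = -q[1]; q[2] = -q[2]; q[3] = -q[3]; }
      break;
    }
  }
}

// Deterministic per-placement score noise: keyed on (crystal seed,
// component, quaternion bins ~5 deg, translation bins 1 A); sd = epsilon*w.
// [[Rcpp::export]]
double cppPlacementNoise(NumericMatrix rot, NumericVector trans, int comp,
                         double w, double epsilon, int seed) {
  if (epsilon <= 0) return 0.0;
  double q[4];
  rotToQuat(REAL(rot), q);
  std::vector<int64_t> key;
  key.push_back(1469598103LL);
  key.push_back(seed);
  key.push_back(comp);
  for (int i = 0; i < 4; ++i) key.push_back((int64_t)std::llround(q[i] / 0.044));
  for (int i = 0; i < 3; ++i) key.push_back((int64_t)std::llround(trans[i]));
  return epsilon * w * hashNormal(key);
}

struct Affine { double A[9]; double b[3]; };

static std::vector<Affine> readOps(List ops) {
  std::vector<Affine> out(ops.size());
  for (int m = 0; m < ops.size(); ++m) {
    List o = ops[m];
    NumericMatrix A = o["A"];
    NumericVector b = o["b"];
    for (int i = 0; i < 9; ++i) out[m].A[i] = A[i];
    for (int i = 0; i < 3; ++i) out[m].b[i] = b[i];
  }
  return out;
}

// Truth record unpacked once: images of the full component cloud under the
// TRUE group, with their centroids.
struct TruthRec {
  int comp;
  std::vector<NumericMatrix> images;
  std::vector<std::vector<double> > icen;
};

static std::vector<TruthRec> readTruths(List truths) {
  std::vector<TruthRec> out(truths.size());
  for (int k = 0; k < truths.size(); ++k) {
    List tr = truths[k];
    out[k].comp = as<int>(tr["comp"]);
    List images = tr["images"];
    for (int m = 0; m < images.size(); ++m) {
      NumericMatrix T = images[m];
      out[k].images.push_back(T);
      std::vector<double> c(3, 0.0);
      for (int i = 0; i < T.nrow(); ++i)
        for (int j = 0; j < 3; ++j) c[j] += T(i, j);
      for (int j = 0; j < 3; ++j) c[j] /= T.nrow();
      out[k].icen.push_back(c);
    }
  }
  return out;
}

// Paired Gaussian overlap of an already-imaged placement (img, col-major
// n x 3) against one truth image, rows selected by res (1-based), with a
// single rigid lattice adjustment taken from the centroid difference.
static double kernelOverlap(const std::vector<double> &img, int n,
                            const double *cp, const NumericMatrix &T,
                            const double *ct, const int *res,
                            const double *orth, const double *frac,
                            double inv2s2) {
  int nT = T.nrow();
  const double *Tp = REAL(const_cast<NumericMatrix &>(T));
  double d[3] = {ct[0] - cp[0], ct[1] - cp[1], ct[2] - cp[2]};
  double df[3], adj[3];
  matvec3(frac, d, df);
  for (int k = 0; k < 3; ++k) df[k] = std::nearbyint(df[k]);
  matvec3(orth, df, adj);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    int r = res[i] - 1;
    double dx = Tp[r] - adj[0] - img[i];
    double dy = Tp[r + nT] - adj[1] - img[i + n];
    double dz = Tp[r + 2 * nT] - adj[2] - img[i + 2 * n];
    s += std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
  }
  return s / n;
}

// minimum-image centroid distance
static double minImageDist(const double *a, const double *b,
                           const double *orth, const double *frac) {
  double d[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double df[3], dc[3];
  matvec3(frac, d, df);
  for (int k = 0; k < 3; ++k) df[k] -= std::nearbyint(df[k]);
  matvec3(orth, df, dc);
  return std::sqrt(dc[0] * dc[0] + dc[1] * dc[1] + dc[2] * dc[2]);
}

// Structure-wise overlap row of one placement against all truths:
// ov[k] = mean over hypothesis-group images of the placement of the best
// kernel overlap against any true-group image of truth k.
static void overlapRow(const double *X, int n, const double *cen,
                       const int *res, int comp, const double *shift,
                       const std::vector<Affine> &hypOps,
                       const std::vector<TruthRec> &truths,
                       const double *orth, const double *frac,
                       double inv2s2, double preCut, double *ovOut) {
  int K = truths.size();
  int M = hypOps.size();
  for (int k = 0; k < K; ++k) ovOut[k] = 0.0;
  std::vector<double> img(3 * n);
  for (int m = 0; m < M; ++m) {
    const Affine &op = hypOps[m];
    double cs[3] = {cen[0] + shift[0], cen[1] + shift[1], cen[2] + shift[2]};
    double cm[3], cy[3];
    matvec3(op.A, cs, cy);
    for (int k = 0; k < 3; ++k) cm[k] = cy[k] + op.b[k];
    bool built = false;
    for (int k = 0; k < K; ++k) {
      if (truths[k].comp != comp) continue;
      double best = 0.0;
      for (size_t t = 0; t < truths[k].images.size(); ++t) {
        if (minImageDist(cm, &truths[k].icen[t][0], orth, frac) > preCut)
          continue;
        if (!built) {
          for (int i = 0; i < n; ++i) {
            double x[3] = {X[i] + shift[0], X[i + n] + shift[1],
                           X[i + 2 * n] + shift[2]};
            double y[3];
            matvec3(op.A, x, y);
            img[i] = y[0] + op.b[0];
            img[i + n] = y[1] + op.b[1];
            img[i + 2 * n] = y[2] + op.b[2];
          }
          built = true;
        }
        double v = kernelOverlap(img, n, cm, truths[k].images[t],
                                 &truths[k].icen[t][0], res, orth, frac,
                                 inv2s2);
        if (v > best) best = v;
      }
      ovOut[k] += best / M;
    }
  }
}

// column-major copy of an R matrix plus centroid
static void unpackCoords(const NumericMatrix &X, std::vector<double> &flat,
                         double *cen) {
  int n = X.nrow();
  flat.resize(3 * n);
  cen[0] = cen[1] = cen[2] = 0;
  for (int i = 0; i < n; ++i) {
    flat[i] = X(i, 0);
    flat[i + n] = X(i, 1);
    flat[i + 2 * n] = X(i, 2);
    cen[0] += X(i, 0); cen[1] += X(i, 1); cen[2] += X(i, 2);
  }
  for (int k = 0; k < 3; ++k) cen[k] /= n;
}

// Overlap matrix (placements x truths) at one global origin shift.
// plc: list of list(coords, res, comp); truths: list of list(comp, images).
// [[Rcpp::export]]
NumericMatrix cppOvMatrix(List plc, List truths, List hypOps,
                          NumericVector shift, NumericMatrix orth,
                          NumericMatrix frac, double sigma) {
  int P = plc.size();
  std::vector<TruthRec> tr = readTruths(truths);
  int K = tr.size();
  NumericMatrix ov(P, K);
  std::vector<Affine> ops = readOps(hypOps);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double preCut = 6.0 * sigma + 5.0;
  for (int p = 0; p < P; ++p) {
    List pl = plc[p];
    NumericMatrix X = pl["coords"];
    IntegerVector res = pl["res"];
    int pc = as<int>(pl["comp"]);
    std::vector<double> flat;
    double cen[3];
    unpackCoords(X, flat, cen);
    std::vector<double> row(K);
    overlapRow(&flat[0], X.nrow(), cen, INTEGER(res), pc, REAL(shift), ops,
               tr, REAL(orth), REAL(frac), inv2s2, preCut, &row[0]);
    for (int k = 0; k < K; ++k) ov(p, k) = row[k];
  }
  return ov;
}

// Greedy best-overlap matching without truth reuse; ties broken by lowest
// placement index then truth index.  Returns 1-based matched truth index per
// placement (0 = unmatched) and the weighted matched sum.
// [[Rcpp::export]]
List cppGreedyMatch(NumericMatrix ov, NumericVector w) {
  int P = ov.nrow(), K = ov.ncol();
  std::vector<bool> pUsed(P, false), kUsed(K, false);
  IntegerVector matched(P, 0);
  NumericVector movl(P, 0.0);
  double total = 0.0;
  for (int it = 0; it < std::min(P, K); ++it) {
    double best = 1e-12;
    int bp = -1, bk = -1;
    for (int p = 0; p < P; ++p) {
      if (pUsed[p]) continue;
      for (int k = 0; k < K; ++k) {
        if (kUsed[k]) continue;
        if (ov(p, k) > best + 1e-15) { best = ov(p, k); bp = p; bk = k; }
      }
    }
    if (bp < 0) break;
    pUsed[bp] = true; kUsed[bk] = true;
    matched[bp] = bk + 1;
    movl[bp] = best;
    total += w[bp] * best;
  }
  return List::create(_["matched"] = matched, _["overlap"] = movl,
                      _["total"] = total);
}

// Pairwise clash counts between placements (and their own non-identity
// images) under the hypothesis group, with per-atom minimum-image wrapping.
// Returns a P x P matrix, filled for j >= i.
// [[Rcpp::export]]
IntegerMatrix cppClashMatrix(List plc, List hypOps, NumericMatrix orth,
                             NumericMatrix frac, double cutoff) {
  int P = plc.size();
  IntegerMatrix clash(P, P);
  std::vector<Affine> ops = readOps(hypOps);
  const double *Om = REAL(orth), *Fm = REAL(frac);
  double cut2 = cutoff * cutoff;

  std::vector<NumericMatrix> X(P);
  std::vector<double> rad(P);
  std::vector<std::vector<double> > cen(P, std::vector<double>(3, 0.0));
  for (int p = 0; p < P; ++p) {
    List pl = plc[p];
    NumericMatrix xx = as<NumericMatrix>(pl["coords"]);
    X[p] = xx;
    for (int i = 0; i < xx.nrow(); ++i)
      for (int k = 0; k < 3; ++k) cen[p][k] += xx(i, k);
    for (int k = 0; k < 3; ++k) cen[p][k] /= xx.nrow();
    double r = 0;
    for (int i = 0; i < xx.nrow(); ++i) {
      double d0 = xx(i, 0) - cen[p][0], d1 = xx(i, 1) - cen[p][1],
             d2 = xx(i, 2) - cen[p][2];
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d > r) r = d;
    }
    rad[p] = std::sqrt(r);
  }

  for (int i = 0; i < P; ++i) {
    for (int j = i; j < P; ++j) {
      int count = 0;
      for (size_t m = 0; m < ops.size(); ++m) {
        if (i == j && m == 0) continue; // identity self-image
        const Affine &op = ops[m];
        double cj[3], cjy[3], cenj[3] = {cen[j][0], cen[j][1], cen[j][2]};
        matvec3(op.A, cenj, cjy);
        for (int k = 0; k < 3; ++k) cj[k] = cjy[k] + op.b[k];
        if (minImageDist(&cen[i][0], cj, Om, Fm) >
            rad[i] + rad[j] + cutoff + 1.0) continue;
        int ni = X[i].nrow(), nj = X[j].nrow();
        for (int a = 0; a < ni; ++a) {
          for (int b = 0; b < nj; ++b) {
            double xb[3] = {X[j](b, 0), X[j](b, 1), X[j](b, 2)}, yb[3];
            matvec3(op.A, xb, yb);
            double dd[3] = {yb[0] + op.b[0] - X[i](a, 0),
                            yb[1] + op.b[1] - X[i](a, 1),
                            yb[2] + op.b[2] - X[i](a, 2)};
            double ddf[3], ddc[3];
            matvec3(Fm, dd, ddf);
            for (int k = 0; k < 3; ++k) ddf[k] -= std::nearbyint(ddf[k]);
            matvec3(Om, ddf, ddc);
            double d2 = ddc[0] * ddc[0] + ddc[1] * ddc[1] + ddc[2] * ddc[2];
            if (d2 < cut2) ++count;
          }
        }
      }
      clash(i, j) = count;
    }
  }
  return clash;
}

// Translation-grid scan: raw score delta of adding one oriented model at
// every grid position to a fixed partial solution, evaluated at the
// partial's cached per-shift overlap rows, including the clash penalty and
// the new placement's deterministic bin noise.
// [[Rcpp::export]]
List cppTranslationScan(NumericMatrix gridT, NumericMatrix model,
                                 IntegerVector res, int comp, double w,
                                 List partialOv, List partialPlc,
                                 NumericVector partialW, List truths,
                                 List hypOps, NumericMatrix shifts,
                                 NumericMatrix orth, NumericMatrix frac,
                                 double sigma, double clashCutoff,
                                 double partialGeo, double epsilon, int seed,
                                 NumericMatrix modelRot) {
  int G = gridT.nrow();
  int n = model.nrow();
  int S = shifts.nrow();
  int P = partialPlc.size();
  std::vector<Affine> ops = readOps(hypOps);
  std::vector<TruthRec> tr = readTruths(truths);
  int K = tr.size();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double preCut = 6.0 * sigma + 5.0;
  double cut2 = clashCutoff * clashCutoff;
  const double *Om = REAL(orth), *Fm = REAL(frac);

  // cache partial coords + centroids/radii for the clash delta
  std::vector<NumericMatrix> PX(P);
  std::vector<std::vector<double> > pcen(P, std::vector<double>(3, 0.0));
  std::vector<double> prad(P, 0.0);
  for (int p = 0; p < P; ++p) {
    List pl = partialPlc[p];
    NumericMatrix xx = as<NumericMatrix>(pl["coords"]);
    PX[p] = xx;
    for (int i = 0; i < xx.nrow(); ++i)
      for (int k = 0; k < 3; ++k) pcen[p][k] += xx(i, k);
    for (int k = 0; k < 3; ++k) pcen[p][k] /= xx.nrow();
    double r = 0;
    for (int i = 0; i < xx.nrow(); ++i) {
      double d0 = xx(i, 0) - pcen[p][0], d1 = xx(i, 1) - pcen[p][1],
             d2 = xx(i, 2) - pcen[p][2];
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d > r) r = d;
    }
    prad[p] = std::sqrt(r);
  }

  std::vector<double> model0;
  double mcen0[3];
  unpackCoords(model, model0, mcen0);
  double mrad = 0;
  for (int i = 0; i < n; ++i) {
    double d0 = model0[i] - mcen0[0], d1 = model0[i + n] - mcen0[1],
           d2 = model0[i + 2 * n] - mcen0[2];
    double d = d0 * d0 + d1 * d1 + d2 * d2;
    if (d > mrad) mrad = d;
  }
  mrad = std::sqrt(mrad);

  std::vector<NumericMatrix> cachedOvM(S);
  std::vector<double> cachedTotal(S, 0.0);
  for (int s = 0; s < S; ++s) {
    cachedOvM[s] = as<NumericMatrix>(partialOv[s]);
    // greedy total of the partial alone at this shift (fast path when the
    // new placement overlaps no truth)
    const double *pv = REAL(cachedOvM[s]);
    std::vector<bool> pUsed(P, false), kUsed(K, false);
    int nit = std::min(P, K);
    for (int it = 0; it < nit; ++it) {
      double best = 1e-12;
      int bp = -1, bk = -1;
      for (int p = 0; p < P; ++p) {
        if (pUsed[p]) continue;
        for (int k = 0; k < K; ++k) {
          if (kUsed[k]) continue;
          double v = pv[p + (size_t)P * k];
          if (v > best + 1e-15) { best = v; bp = p; bk = k; }
        }
      }
      if (bp < 0) break;
      pUsed[bp] = true; kUsed[bk] = true;
      cachedTotal[s] += partialW[bp] * best;
    }
  }

  double wsum = w;
  for (int p = 0; p < P; ++p) wsum += partialW[p];
  double wbarNew = wsum / (P + 1);

  NumericVector raw(G);
  LogicalVector clashFree(G);
  std::vector<double> X(3 * n), ovNew(K);

  for (int g = 0; g < G; ++g) {
    double tx = gridT(g, 0), ty = gridT(g, 1), tz = gridT(g, 2);
    for (int i = 0; i < n; ++i) {
      X[i] = model0[i] + tx;
      X[i + n] = model0[i + n] + ty;
      X[i + 2 * n] = model0[i + 2 * n] + tz;
    }
    double mcen[3] = {mcen0[0] + tx, mcen0[1] + ty, mcen0[2] + tz};

    // clash delta: new placement vs partials (all ops) and own images
    int clashNew = 0;
    for (int p = -1; p < P; ++p) {
      const double *yc = (p < 0) ? mcen : &pcen[p][0];
      double yr = (p < 0) ? mrad : prad[p];
      int nY = (p < 0) ? n : PX[p].nrow();
      for (size_t m = 0; m < ops.size(); ++m) {
        if (p < 0 && m == 0) continue;
        const Affine &op = ops[m];
        double cj[3], cjy[3], ycen[3] = {yc[0], yc[1], yc[2]};
        matvec3(op.A, ycen, cjy);
        for (int k = 0; k < 3; ++k) cj[k] = cjy[k] + op.b[k];
        if (minImageDist(mcen, cj, Om, Fm) > mrad + yr + clashCutoff + 1.0)
          continue;
        for (int a = 0; a < n; ++a) {
          for (int b = 0; b < nY; ++b) {
            double xb[3], yb[3];
            if (p < 0) {
              xb[0] = X[b]; xb[1] = X[b + n]; xb[2] = X[b + 2 * n];
            } else {
              xb[0] = PX[p](b, 0); xb[1] = PX[p](b, 1); xb[2] = PX[p](b, 2);
            }
            matvec3(op.A, xb, yb);
            double dd[3] = {yb[0] + op.b[0] - X[a],
                            yb[1] + op.b[1] - X[a + n],
                            yb[2] + op.b[2] - X[a + 2 * n]};
            double ddf[3], ddc[3];
            matvec3(Fm, dd, ddf);
            for (int k = 0; k < 3; ++k) ddf[k] -= std::nearbyint(ddf[k]);
            matvec3(Om, ddf, ddc);
            double d2 = ddc[0] * ddc[0] + ddc[1] * ddc[1] + ddc[2] * ddc[2];
            if (d2 < cut2) ++clashNew;
          }
        }
      }
    }

    // best over candidate shifts of the greedy-matched weighted sum
    double bestScore = -1e300;
    for (int s = 0; s < S; ++s) {
      double shift[3] = {shifts(s, 0), shifts(s, 1), shifts(s, 2)};
      overlapRow(&X[0], n, mcen, INTEGER(res), comp, shift, ops, tr,
                 Om, Fm, inv2s2, preCut, &ovNew[0]);
      double maxNew = 0.0;
      for (int k = 0; k < K; ++k) if (ovNew[k] > maxNew) maxNew = ovNew[k];
      if (maxNew <= 1e-12) {
        if (cachedTotal[s] > bestScore) bestScore = cachedTotal[s];
        continue;
      }
      const double *pv = REAL(cachedOvM[s]);
      std::vector<bool> pUsed(P + 1, false), kUsed(K, false);
      double total = 0.0;
      int nit = std::min(P + 1, K);
      for (int it = 0; it < nit; ++it) {
        double best = 1e-12;
        int bp = -1, bk = -1;
        for (int p = 0; p <= P; ++p) {
          if (pUsed[p]) continue;
          for (int k = 0; k < K; ++k) {
            if (kUsed[k]) continue;
            double v = (p < P) ? pv[p + (size_t)P * k] : ovNew[k];
            if (v > best + 1e-15) { best = v; bp = p; bk = k; }
          }
        }
        if (bp < 0) break;
        pUsed[bp] = true; kUsed[bk] = true;
        total += ((bp < P) ? partialW[bp] : w) * best;
      }
      if (total > bestScore) bestScore = total;
    }

    double combined = bestScore - 0.5 * wbarNew * clashNew;
    NumericVector tv = NumericVector::create(tx, ty, tz);
    double noise = cppPlacementNoise(modelRot, tv, comp, w, epsilon, seed);
    raw[g] = combined - partialGeo + noise;
    clashFree[g] = (clashNew == 0);
  }
  return List::create(_["raw"] = raw, _["clashFree"] = clashFree);
}
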