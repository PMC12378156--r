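#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// reflect-101 index for mirror padding
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// quantize window values (min-max, `levels` bins); constant window -> level 0
static void quantize(const std::vector<double>& v, int levels,
                     std::vector<int>& q) {
  double lo = v[0], hi = v[0];
  for (double x : v) { if (x < lo) lo = x; if (x > hi) hi = x; }
  const double span = hi - lo;
  for (size_t k = 0; k < v.size(); ++k) {
    if (span < 1e-300) { q[k] = 0; continue; }
    int g = (int)std::floor((v[k] - lo) / span * levels);
    if (g >= levels) g = levels - 1;
    if (g < 0) g = 0;
    q[k] = g;
  }
}

struct GlcmStats { double me, va, ho, co, di, en, sm, cr; };

// accumulate symmetric co-occurrence over offsets and compute the eight
// Haralick-type statistics; P is implicit (dense levels x levels counts)
static GlcmStats window_stats(const std::vector<int>& q, int w, int levels,
                              const IntegerMatrix& offsets,
                              std::vector<double>& P) {
  std::fill(P.begin(), P.end(), 0.0);
  double tot = 0.0;
  for (int o = 0; o < offsets.nrow(); ++o) {
    const int dr = offsets(o, 0), dc = offsets(o, 1);
    for (int r = 0; r < w; ++r) {
      const int r2 = r + dr;
      if (r2 < 0 || r2 >= w) continue;
      for (int c = 0; c < w; ++c) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= w) continue;
        const int a = q[r + w * c], b = q[r2 + w * c2];
        P[a + levels * b] += 1.0;
        P[b + levels * a] += 1.0;
        tot += 2.0;
      }
    }
  }
  GlcmStats s; s.me = s.va = s.ho = s.co = s.di = s.en = s.sm = 0.0;
  s.cr = NA_REAL;
  if (tot <= 0) return s;
  double mu = 0.0;
  for (int i = 0; i < levels; ++i)
    for (int j = 0; j < levels; ++j) {
      const double p = P[i + levels * j] / tot;
      if (p <= 0) continue;
      mu += i * p;
      const int d = i - j;
      s.ho += p / (1.0 + d * d);
      s.co += p * d * d;
      s.di += p * std::abs(d);
      s.en += -p * std::log(p);
      s.sm += p * p;
    }
  double va = 0.0, cov = 0.0;
  for (int i = 0; i < levels; ++i)
    for (int j = 0; j < levels; ++j) {
      const double p = P[i + levels * j] / tot;
      if (p <= 0) continue;
      va += (i - mu) * (i - mu) * p;
      cov += (i - mu) * (j - mu) * p;
    }
  s.me = mu; s.va = va;
  if (va > 1e-15) s.cr = cov / va;  // symmetric P: sd_i == sd_j
  return s;
}

// [[Rcpp::export]]
NumericMatrix glcm_window_cpp(NumericMatrix values, int levels,
                              IntegerMatrix offsets) {
  const int nr = values.nrow(), nc = values.ncol();
  std::vector<double> v(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) v[r + nr * c] = values(r, c);
  std::vector<int> q(v.size());
  quantize(v, levels, q);
  NumericMatrix P(levels, levels);
  double tot = 0.0;
  for (int o = 0; o < offsets.nrow(); ++o) {
    const int dr = offsets(o, 0), dc = offsets(o, 1);
    for (int r = 0; r < nr; ++r) {
      const int r2 = r + dr;
      if (r2 < 0 || r2 >= nr) continue;
      for (int c = 0; c < nc; ++c) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= nc) continue;
        const int a = q[r + nr * c], b = q[r2 + nr * c2];
        P(a, b) += 1.0; P(b, a) += 1.0; tot += 2.0;
      }
    }
  }
  if (tot > 0) for (int k = 0; k < levels * levels; ++k) P[k] /= tot;
  return P;
}

// [[Rcpp::export]]
List glcm_grid_cpp(NumericMatrix band, int window, int levels,
                   IntegerMatrix offsets) {
  const int nr = band.nrow(), nc = band.ncol();
  const int h = window / 2, w = window;
  NumericMatrix ME(nr, nc), VA(nr, nc), HO(nr, nc), CO(nr, nc),
      DI(nr, nc), EN(nr, nc), SM(nr, nc), CR(nr, nc);
  std::vector<double> v(w * w), P((size_t)levels * levels);
  std::vector<int> q(w * w);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int wc = 0; wc < w; ++wc) {
        const int cc = refl(c + wc - h, nc);
        for (int wr = 0; wr < w; ++wr) {
          const int rr = refl(r + wr - h, nr);
          v[wr + w * wc] = band(rr, cc);
        }
      }
      quantize(v, levels, q);
      const GlcmStats s = window_stats(q, w, levels, offsets, P);
      ME(r, c) = s.me; VA(r, c) = s.va; HO(r, c) = s.ho; CO(r, c) = s.co;
      DI(r, c) = s.di; EN(r, c) = s.en; SM(r, c) = s.sm; CR(r, c) = s.cr;
    }
  }
  return List::create(ME, VA, HO, CO, DI, EN, SM, CR);
}
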