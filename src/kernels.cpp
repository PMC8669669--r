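#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-neighborhood offsets, clockwise from top-left.
// Index:     0        1       2       3      4      5      6       7
static const int NDR[8] = {-1, -1, -1,  0,  1, 1, 1,  0};
static const int NDC[8] = {-1,  0,  1,  1,  1, 0, -1, -1};

// Lookup table over the 256 possible 8-neighborhood configurations:
// simple_lut[cfg] is true when the center pixel is a simple point under
// 8-connected foreground / 4-connected background, i.e. its removal
// preserves both component count and holes (hence the Euler number).
static bool simple_lut[256];
static bool lut_ready = false;

static int ring_components(int cfg, bool fg, bool conn8, bool require4) {
  // Count connected components among the 8 ring positions whose value
  // matches fg, using 8- or 4-adjacency between positions. If require4,
  // count only components containing an edge-neighbor (indices 1,3,5,7).
  bool val[8];
  for (int i = 0; i < 8; ++i) val[i] = ((cfg >> i) & 1) != 0;
  int comp[8];
  for (int i = 0; i < 8; ++i) comp[i] = -1;
  int ncomp = 0, counted = 0;
  for (int s = 0; s < 8; ++s) {
    if (val[s] != fg || comp[s] >= 0) continue;
    // BFS over ring positions
    std::queue<int> q;
    q.push(s); comp[s] = ncomp;
    bool has4 = false;
    while (!q.empty()) {
      int i = q.front(); q.pop();
      if (i % 2 == 1) has4 = true;
      for (int j = 0; j < 8; ++j) {
        if (val[j] != fg || comp[j] >= 0) continue;
        int ddr = NDR[i] - NDR[j], ddc = NDC[i] - NDC[j];
        int cheb = std::max(std::abs(ddr), std::abs(ddc));
        int manh = std::abs(ddr) + std::abs(ddc);
        bool adj = conn8 ? (cheb == 1) : (manh == 1);
        if (adj) { comp[j] = ncomp; q.push(j); }
      }
    }
    ++ncomp;
    if (!require4 || has4) ++counted;
  }
  return counted;
}

static void build_lut() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    int cstar = ring_components(cfg, true, true, false);   // fg, 8-adj
    int cbar  = ring_components(cfg, false, false, true);  // bg, 4-adj, must touch an edge-neighbor
    simple_lut[cfg] = (cstar == 1 && cbar == 1);
  }
  lut_ready = true;
}

static inline int neighbor_cfg(const LogicalMatrix& m, int r, int c) {
  int H = m.nrow(), W = m.ncol(), cfg = 0;
  for (int i = 0; i < 8; ++i) {
    int rr = r + NDR[i], cc = c + NDC[i];
    if (rr >= 0 && rr < H && cc >= 0 && cc < W && m(rr, cc)) cfg |= (1 << i);
  }
  return cfg;
}

static inline int popcount8(int cfg) {
  int n = 0;
  for (int i = 0; i < 8; ++i) n += (cfg >> i) & 1;
  return n;
}

//' @noRd
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  if (!lut_ready) build_lut();
  LogicalMatrix m = clone(mask);
  int H = m.nrow(), W = m.ncol();
  // Border direction per subpass: neighbor index that must be background
  // (N, S, E, W edge neighbors: cfg indices 1, 5, 3, 7).
  static const int passes[4] = {1, 5, 3, 7};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int p = 0; p < 4; ++p) {
      int bidx = passes[p];
      // freeze the directional border candidates at pass start, then delete
      // sequentially, re-checking simplicity against the current image so
      // every single removal is of a simple point (topology-safe)
      std::vector<int> cand;
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!m(r, c)) continue;
          int cfg = neighbor_cfg(m, r, c);
          if ((cfg >> bidx) & 1) continue;      // not a border pixel in this direction
          cand.push_back(r + c * H);
        }
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int r = cand[k] % H, c = cand[k] / H;
        if (!m(r, c)) continue;
        int cfg = neighbor_cfg(m, r, c);
        int nn = popcount8(cfg);
        if (nn <= 1) continue;                  // endpoint or isolated: keep
        if (simple_lut[cfg]) {
          m(r, c) = false;
          changed = true;
        }
      }
    }
  }
  return m;
}

//' @noRd
// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int nlab = 0;
  int ndir = (connectivity == 8) ? 8 : 4;
  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++nlab;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = nlab;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int d = 0; d < ndir; ++d) {
          int nr, nc;
          if (connectivity == 8) { nr = rr + NDR[d]; nc = cc + NDC[d]; }
          else { nr = rr + DR4[d]; nc = cc + DC4[d]; }
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (!mask(nr, nc) || lab(nr, nc)) continue;
          lab(nr, nc) = nlab;
          stack.push_back(nr + nc * H);
        }
      }
    }
  }
  lab.attr("n") = nlab;
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".stamp_particles_cpp")]]
NumericMatrix stamp_particles_cpp(NumericMatrix img, NumericVector pr,
                                  NumericVector pc, NumericVector radius,
                                  NumericVector amp) {
  // Subtract a dark disc (absorbance stamp) per particle; img modified copy.
  // pr/pc are 0-based real coordinates.
  NumericMatrix out = clone(img);
  int H = out.nrow(), W = out.ncol();
  int n = pr.size();
  for (int k = 0; k < n; ++k) {
    double r = radius[k], a = amp[k];
    int r0 = std::max(0, (int)std::floor(pr[k] - r));
    int r1 = std::min(H - 1, (int)std::ceil(pr[k] + r));
    int c0 = std::max(0, (int)std::floor(pc[k] - r));
    int c1 = std::min(W - 1, (int)std::ceil(pc[k] + r));
    double r2 = r * r;
    for (int c = c0; c <= c1; ++c) {
      for (int rr = r0; rr <= r1; ++rr) {
        double dr = rr - pr[k], dc = c - pc[k];
        if (dr * dr + dc * dc <= r2) {
          out(rr, c) -= a;
          if (out(rr, c) < 0) out(rr, c) = 0;
        }
      }
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".stroke_segment_cpp")]]
LogicalMatrix stroke_segment_cpp(LogicalMatrix mask, NumericMatrix poly,
                                 double radius) {
  // Set mask pixels within `radius` of the polyline (0-based coords) to TRUE.
  LogicalMatrix out = clone(mask);
  int H = out.nrow(), W = out.ncol();
  int np = poly.nrow();
  for (int s = 0; s + 1 < np; ++s) {
    double ar = poly(s, 0), ac = poly(s, 1);
    double br = poly(s + 1, 0), bc = poly(s + 1, 1);
    double vr = br - ar, vc = bc - ac;
    double len2 = vr * vr + vc * vc;
    int r0 = std::max(0, (int)std::floor(std::min(ar, br) - radius));
    int r1 = std::min(H - 1, (int)std::ceil(std::max(ar, br) + radius));
    int c0 = std::max(0, (int)std::floor(std::min(ac, bc) - radius));
    int c1 = std::min(W - 1, (int)std::ceil(std::max(ac, bc) + radius));
    double rad2 = radius * radius;
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double t = 0.0;
        if (len2 > 0) {
          t = ((r - ar) * vr + (c - ac) * vc) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        double dr = r - (ar + t * vr), dc = c - (ac + t * vc);
        if (dr * dr + dc * dc <= rad2) out(r, c) = true;
      }
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".zncc_scan_cpp")]]
NumericMatrix zncc_scan_cpp(NumericMatrix ref, NumericMatrix frame,
                            int pr0, int pc0,
                            int dr_min, int dr_max, int dc_min, int dc_max) {
  // Zero-normalized cross-correlation of ref against the like-sized window
  // of frame placed at (pr0 + dr, pc0 + dc), 0-based top-left coordinates.
  // Out-of-frame candidates score NA.
  int h = ref.nrow(), w = ref.ncol();
  int H = frame.nrow(), W = frame.ncol();
  int ndr = dr_max - dr_min + 1, ndc = dc_max - dc_min + 1;
  NumericMatrix out(ndr, ndc);
  std::fill(out.begin(), out.end(), NA_REAL);
  double n = (double)h * w;
  double rmean = 0.0;
  for (int j = 0; j < w; ++j) for (int i = 0; i < h; ++i) rmean += ref(i, j);
  rmean /= n;
  double rss = 0.0;
  for (int j = 0; j < w; ++j) for (int i = 0; i < h; ++i) {
    double d = ref(i, j) - rmean; rss += d * d;
  }
  double rsd = std::sqrt(rss);
  for (int a = 0; a < ndr; ++a) {
    int dr = dr_min + a;
    int r0 = pr0 + dr;
    if (r0 < 0 || r0 + h > H) continue;
    for (int b = 0; b < ndc; ++b) {
      int dc = dc_min + b;
      int c0 = pc0 + dc;
      if (c0 < 0 || c0 + w > W) continue;
      double fsum = 0.0, fss = 0.0, cross = 0.0;
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          double f = frame(r0 + i, c0 + j);
          fsum += f; fss += f * f;
          cross += f * (ref(i, j) - rmean);
        }
      }
      double fmean = fsum / n;
      double fvar = fss - n * fmean * fmean;
      if (fvar < 0) fvar = 0;
      double fsd = std::sqrt(fvar);
      if (rsd == 0.0 || fsd == 0.0) {
        // flat patch or window: correlation undefined; report 0
        out(a, b) = 0.0;
      } else {
        // cross already uses centered ref, so subtracting window mean is implicit
        out(a, b) = cross / (rsd * fsd);
      }
    }
  }
  return out;
}
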