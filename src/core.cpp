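#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Disk-neighbourhood median filter with edge replication.
// `img` holds intensities (any numeric range); the neighbourhood is the set
// of offsets with dx^2 + dy^2 <= radius^2, which for radius 2 has 13 pixels.
// [[Rcpp::export(name = ".cpp_disk_median")]]
NumericMatrix cpp_disk_median(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  const int K = (int)dy.size();
  std::vector<double> buf(K);
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      for (int k = 0; k < K; ++k) {
        int ii = i + dy[k]; if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        int jj = j + dx[k]; if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        buf[k] = img(ii, jj);
      }
      int mid = K / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (K % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        m = 0.5 * (m + buf[mid - 1]);
      }
      out(i, j) = m;
    }
  }
  return out;
}

static inline int nb_sum(const std::vector<unsigned char> &p) {
  int s = 0;
  for (int k = 0; k < 8; ++k) s += p[k];
  return s;
}

static inline int nb_transitions(const std::vector<unsigned char> &p) {
  // 0->1 transitions in the cyclic sequence p2,p3,...,p9,p2
  int a = 0;
  for (int k = 0; k < 8; ++k)
    if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
  return a;
}

// neighbourhood offsets in the cyclic order N, NE, E, SE, S, SW, W, NW
static const int NB_DI[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int NB_DJ[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// T8: number of 8-connected components of the foreground neighbours,
// using their true spatial adjacency inside the 3x3 window.
static int t8_components(const std::vector<unsigned char> &p) {
  int comp[8];
  for (int k = 0; k < 8; ++k) comp[k] = p[k] ? k : -1;
  bool merged = true;
  while (merged) {
    merged = false;
    for (int a = 0; a < 8; ++a) {
      if (comp[a] < 0) continue;
      for (int b = a + 1; b < 8; ++b) {
        if (comp[b] < 0 || comp[b] == comp[a]) continue;
        int di = NB_DI[a] - NB_DI[b], dj = NB_DJ[a] - NB_DJ[b];
        if (di >= -1 && di <= 1 && dj >= -1 && dj <= 1) {
          int from = comp[b], to = comp[a];
          for (int c = 0; c < 8; ++c) if (comp[c] == from) comp[c] = to;
          merged = true;
        }
      }
    }
  }
  int n = 0;
  bool seen[8] = {false, false, false, false, false, false, false, false};
  for (int k = 0; k < 8; ++k)
    if (comp[k] >= 0 && !seen[comp[k]]) { seen[comp[k]] = true; ++n; }
  return n;
}

// Deleting p keeps its foreground neighbours mutually connected iff they
// form a single 8-component. (Background topology is deliberately not
// protected here: the only pixels deleted under this test are members of
// 2x2 blocks, where preserving one-pixel speckle holes would defeat the
// unit-width guarantee.)
static inline bool fg_safe_to_delete(const std::vector<unsigned char> &p) {
  return t8_components(p) == 1;
}

// Zhang-Suen iterative thinning to a 1-pixel, 8-connected skeleton.
// Deletion only: the result is always a subset of the input mask.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img((size_t)H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      img[(size_t)j * H + i] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> unsigned char {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return img[(size_t)j * H + i];
  };
  std::vector<unsigned char> p(8);
  // Candidate-driven iteration: a pixel can only become deletable when its
  // neighbourhood changes, so after the first full pass it suffices to
  // revisit the neighbours of deleted pixels. Results are identical to the
  // full-scan algorithm.
  std::vector<size_t> cand, del, next_cand;
  std::vector<unsigned char> in_next((size_t)H * W, 0);
  cand.reserve((size_t)H * W);
  for (size_t k = 0; k < img.size(); ++k)
    if (img[k]) cand.push_back(k);
  bool changed = true;
  while (changed) {
    changed = false;
    next_cand.clear();
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      // sub 2 additionally revisits neighbours of sub-1 deletions so the
      // result matches a full-image scan exactly
      size_t n_scan = cand.size() + (sub == 1 ? next_cand.size() : 0);
      for (size_t c = 0; c < n_scan; ++c) {
        size_t k = c < cand.size() ? cand[c] : next_cand[c - cand.size()];
        if (!img[k]) continue;
        int i = (int)(k % H), j = (int)(k / H);
        // p2..p9 = N, NE, E, SE, S, SW, W, NW
        p[0] = at(i - 1, j);     p[1] = at(i - 1, j + 1);
        p[2] = at(i, j + 1);     p[3] = at(i + 1, j + 1);
        p[4] = at(i + 1, j);     p[5] = at(i + 1, j - 1);
        p[6] = at(i, j - 1);     p[7] = at(i - 1, j - 1);
        int B = nb_sum(p);
        if (B < 2 || B > 6) continue;
        if (nb_transitions(p) != 1) continue;
        if (sub == 0) {
          if (p[0] * p[2] * p[4] != 0) continue;   // p2*p4*p6
          if (p[2] * p[4] * p[6] != 0) continue;   // p4*p6*p8
        } else {
          if (p[0] * p[2] * p[6] != 0) continue;   // p2*p4*p8
          if (p[0] * p[4] * p[6] != 0) continue;   // p2*p6*p8
        }
        del.push_back(k);
      }
      for (size_t d = 0; d < del.size(); ++d) {
        size_t k = del[d];
        img[k] = 0;
        int i = (int)(k % H), j = (int)(k / H);
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            size_t kk = (size_t)jj * H + ii;
            if (!in_next[kk]) { in_next[kk] = 1; next_cand.push_back(kk); }
          }
        }
      }
      if (!del.empty()) changed = true;
    }
    cand = next_cand;
    for (size_t c = 0; c < cand.size(); ++c) in_next[cand[c]] = 0;

    if (!changed) {
      // Zhang-Suen can leave 2x2 blocks (staircases, diagonal crossings).
      // Prefer deleting a block member whose foreground neighbours stay
      // mutually connected; at a crossing of two diagonal unit-width lines
      // no such member exists, and the unit-width guarantee takes priority:
      // the member with the fewest neighbours outside the block is removed,
      // opening one diagonal contact by a single pixel. Thinning then
      // resumes around the deletions so the operator runs to a fixed point.
      next_cand.clear();
      for (int j = 0; j + 1 < W; ++j) {
        for (int i = 0; i + 1 < H; ++i) {
          if (!(at(i, j) && at(i + 1, j) && at(i, j + 1) && at(i + 1, j + 1)))
            continue;
          const int bi[4] = {i, i + 1, i, i + 1};
          const int bj[4] = {j, j, j + 1, j + 1};
          int pick = -1, best_deg = 9;
          for (int q = 0; q < 4; ++q) {
            int ii = bi[q], jj = bj[q];
            p[0] = at(ii - 1, jj);     p[1] = at(ii - 1, jj + 1);
            p[2] = at(ii, jj + 1);     p[3] = at(ii + 1, jj + 1);
            p[4] = at(ii + 1, jj);     p[5] = at(ii + 1, jj - 1);
            p[6] = at(ii, jj - 1);     p[7] = at(ii - 1, jj - 1);
            if (fg_safe_to_delete(p)) { pick = q; break; }
            int deg = nb_sum(p) - 3;   // neighbours outside the block
            if (deg < best_deg) { best_deg = deg; pick = q; }
          }
          if (pick >= 0) {
            int ii = bi[pick], jj = bj[pick];
            img[(size_t)jj * H + ii] = 0;
            changed = true;
            for (int dj = -1; dj <= 1; ++dj) {
              for (int di = -1; di <= 1; ++di) {
                int i2 = ii + di, j2 = jj + dj;
                if (i2 < 0 || i2 >= H || j2 < 0 || j2 >= W) continue;
                size_t kk = (size_t)j2 * H + i2;
                if (!in_next[kk]) { in_next[kk] = 1; next_cand.push_back(kk); }
              }
            }
          }
        }
      }
      cand = next_cand;
      for (size_t c = 0; c < cand.size(); ++c) in_next[cand[c]] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = img[(size_t)j * H + i] != 0;
  return out;
}

// Count occupied eps x eps boxes for one grid offset (oy, ox) in [0, eps)^2.
// The grid origin sits at (-oy, -ox), so partial boxes at all four edges
// participate. Coordinates are 0-based, row-major.
// [[Rcpp::export(name = ".cpp_box_count_one")]]
double cpp_box_count_one(LogicalMatrix skel, int eps, int oy, int ox) {
  const int H = skel.nrow(), W = skel.ncol();
  const int nby = (H + oy + eps - 1) / eps;
  const int nbx = (W + ox + eps - 1) / eps;
  std::vector<unsigned char> occ((size_t)nby * nbx, 0);
  for (int j = 0; j < W; ++j) {
    int bx = (j + ox) / eps;
    for (int i = 0; i < H; ++i) {
      if (skel(i, j)) occ[(size_t)bx * nby + (i + oy) / eps] = 1;
    }
  }
  long long n = 0;
  for (size_t k = 0; k < occ.size(); ++k) n += occ[k];
  return (double)n;
}

// Gliding-box first and second moments of window mass for each window size r.
// Windows glide with step 1 over all fully contained positions; returns per r
// the number of windows, mean mass and mean squared mass.
// [[Rcpp::export(name = ".cpp_gliding_box")]]
NumericMatrix cpp_gliding_box(LogicalMatrix skel, IntegerVector sizes) {
  const int H = skel.nrow(), W = skel.ncol();
  // summed-area table, (H+1) x (W+1)
  std::vector<long long> S((size_t)(H + 1) * (W + 1), 0);
  for (int j = 1; j <= W; ++j)
    for (int i = 1; i <= H; ++i)
      S[(size_t)j * (H + 1) + i] = (skel(i - 1, j - 1) ? 1LL : 0LL)
        + S[(size_t)(j - 1) * (H + 1) + i]
        + S[(size_t)j * (H + 1) + i - 1]
        - S[(size_t)(j - 1) * (H + 1) + i - 1];
  NumericMatrix out(sizes.size(), 4); // r, n_windows, mean M, mean M^2
  for (int s = 0; s < sizes.size(); ++s) {
    const int r = sizes[s];
    out(s, 0) = r;
    if (r > H || r > W) { out(s, 1) = 0; out(s, 2) = NA_REAL; out(s, 3) = NA_REAL; continue; }
    const long long nw = (long long)(H - r + 1) * (W - r + 1);
    long double sum1 = 0, sum2 = 0;
    for (int j = 0; j + r <= W; ++j) {
      for (int i = 0; i + r <= H; ++i) {
        long long m = S[(size_t)(j + r) * (H + 1) + i + r]
          - S[(size_t)j * (H + 1) + i + r]
          - S[(size_t)(j + r) * (H + 1) + i]
          + S[(size_t)j * (H + 1) + i];
        sum1 += m;
        sum2 += (long double)m * m;
      }
    }
    out(s, 1) = (double)nw;
    out(s, 2) = (double)(sum1 / nw);
    out(s, 3) = (double)(sum2 / nw);
  }
  return out;
}
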