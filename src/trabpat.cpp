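#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// Connected-component labeling with selectable pixel connectivity.
// conn = 8 (trabecular/white convention) or 4 (intertrabecular/black),
// the standard digital-topology duality. Labels are 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int conn) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (conn == 8) ? dr8 : dr4;
  const int *dc = (conn == 8) ? dc8 : dc4;
  const int nd = (conn == 8) ? 8 : 4;
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      lab(r0, c0) = ++next;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nd; ++k) {
          int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (mask(r, c) && !lab(r, c)) {
            lab(r, c) = next;
            stack.push_back(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// 3x3 median filter with edge replication (borders clamp to the image).
// [[Rcpp::export]]
NumericMatrix cpp_median3x3(const NumericMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = std::min(std::max(c + dc, 0), nc - 1);
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = std::min(std::max(r + dr, 0), nr - 1);
          w[k++] = x(rr, cc);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(r, c) = w[4];
    }
  }
  return out;
}

// Square mean (box) filter of odd side `win` with edge replication.
// Separable: replicate-padded box filtering factors into a column pass
// and a row pass, each done exactly with prefix sums plus clamp terms.
static void box_pass_cols(const NumericMatrix& x, NumericMatrix& out, int h) {
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<double> pre(nr + 1);
  for (int c = 0; c < nc; ++c) {
    pre[0] = 0.0;
    for (int r = 0; r < nr; ++r) pre[r + 1] = pre[r] + x(r, c);
    for (int r = 0; r < nr; ++r) {
      int lo = r - h, hi = r + h;
      double s = 0.0;
      if (lo < 0) { s += (double)(-lo) * x(0, c); lo = 0; }
      if (hi > nr - 1) { s += (double)(hi - (nr - 1)) * x(nr - 1, c); hi = nr - 1; }
      s += pre[hi + 1] - pre[lo];
      out(r, c) = s;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& x, int win) {
  if (win < 1 || win % 2 == 0) stop("box window must be odd and >= 1");
  const int h = win / 2;
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  box_pass_cols(x, tmp, h);
  NumericMatrix tmpt(nc, nr), outt(nc, nr);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) tmpt(c, r) = tmp(r, c);
  box_pass_cols(tmpt, outt, h);
  const double denom = (double)win * (double)win;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) out(r, c) = outt(c, r) / denom;
  return out;
}

// Guo-Hall topology-preserving thinning to a 1-px, 8-connected skeleton.
// Two sub-iterations per pass; deletions applied simultaneously.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // pad by one to make neighbor access branch-free
  std::vector<unsigned char> img((nr + 2) * (nc + 2), 0);
  std::vector<unsigned char> del((nr + 2) * (nc + 2), 0);
  const int stride = nr + 2;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img[(r + 1) + (c + 1) * stride] = mask(r, c) ? 1 : 0;

  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      for (int c = 1; c <= nc; ++c) {
        for (int r = 1; r <= nr; ++r) {
          int i = r + c * stride;
          if (!img[i]) { del[i] = 0; continue; }
          // neighborhood: p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW
          // rows grow southward, columns grow eastward
          int p2 = img[i - 1];
          int p3 = img[i - 1 + stride];
          int p4 = img[i + stride];
          int p5 = img[i + 1 + stride];
          int p6 = img[i + 1];
          int p7 = img[i + 1 - stride];
          int p8 = img[i - stride];
          int p9 = img[i - 1 - stride];
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                              : ((p2 | p3 | (!p5)) & p4);
          del[i] = (C == 1 && N >= 2 && N <= 3 && m == 0) ? 1 : 0;
        }
      }
      for (int c = 1; c <= nc; ++c) {
        for (int r = 1; r <= nr; ++r) {
          int i = r + c * stride;
          if (del[i]) { img[i] = 0; del[i] = 0; changed = true; }
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img[(r + 1) + (c + 1) * stride] != 0;
  return out;
}

// Skeleton census and strut enumeration on a 1-px skeleton.
// endpoint: exactly 1 skeleton neighbor (8-neighborhood);
// node: >= 3 neighbors; struts: maximal paths between such terminals,
// orthogonal step 1, diagonal step sqrt(2). Pure cycles (no terminal)
// count as one strut each; isolated pixels are neither.
// [[Rcpp::export]]
List cpp_strut_stats(const LogicalMatrix& skel) {
  const int nr = skel.nrow(), nc = skel.ncol();
  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> deg(nr * nc, -1); // -1 = not skeleton
  std::vector<int> px;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!skel(r, c)) continue;
      int d = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (skel(rr, cc)) ++d;
      }
      deg[r + c * nr] = d;
      px.push_back(r + c * nr);
    }
  }
  int nodes = 0, endpoints = 0, isolated = 0;
  for (size_t j = 0; j < px.size(); ++j) {
    int d = deg[px[j]];
    if (d == 0) ++isolated;
    else if (d == 1) ++endpoints;
    else if (d >= 3) ++nodes;
  }
  const double SQ2 = 1.4142135623730951;
  std::unordered_set<long long> seen; // undirected edges, keyed min*N+max
  const long long NN = (long long)nr * nc;
  int strut_count = 0;
  double total_len = 0.0;
  std::vector<double> lens;

  // walk from every terminal along each incident edge
  for (size_t j = 0; j < px.size(); ++j) {
    int t = px[j];
    int d = deg[t];
    if (d == 0 || d == 2) continue; // not a terminal
    int tr = t % nr, tc = t / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = tr + dr[k], cc = tc + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int n = rr + cc * nr;
      if (deg[n] < 0) continue;
      long long key = (t < n) ? (long long)t * NN + n : (long long)n * NN + t;
      if (seen.count(key)) continue;
      seen.insert(key);
      double len = (tr != rr && tc != cc) ? SQ2 : 1.0;
      int prev = t, cur = n;
      while (deg[cur] == 2) {
        int cr = cur % nr, ccol = cur / nr;
        int nxt = -1;
        for (int q = 0; q < 8; ++q) {
          int r2 = cr + dr[q], c2 = ccol + dc[q];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int cand = r2 + c2 * nr;
          if (deg[cand] < 0 || cand == prev) continue;
          nxt = cand;
          break;
        }
        if (nxt < 0) break; // degenerate: both neighbors are prev
        long long k2 = (cur < nxt) ? (long long)cur * NN + nxt
                                   : (long long)nxt * NN + cur;
        if (seen.count(k2)) break; // closed back on itself
        seen.insert(k2);
        int r2 = nxt % nr, c2 = nxt / nr;
        len += (cr != r2 && ccol != c2) ? SQ2 : 1.0;
        prev = cur;
        cur = nxt;
      }
      ++strut_count;
      total_len += len;
      lens.push_back(len);
    }
  }

  // pure cycles: degree-2 pixels none of whose edges were walked
  for (size_t j = 0; j < px.size(); ++j) {
    int s = px[j];
    if (deg[s] != 2) continue;
    int sr = s % nr, sc = s / nr;
    bool touched = false;
    int first = -1;
    for (int k = 0; k < 8; ++k) {
      int rr = sr + dr[k], cc = sc + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int n = rr + cc * nr;
      if (deg[n] < 0) continue;
      long long key = (s < n) ? (long long)s * NN + n : (long long)n * NN + s;
      if (seen.count(key)) { touched = true; break; }
      if (first < 0) first = n;
    }
    if (touched || first < 0) continue;
    // trace the cycle
    double len = 0.0;
    int prev = s, cur = first;
    long long key0 = (s < first) ? (long long)s * NN + first
                                 : (long long)first * NN + s;
    seen.insert(key0);
    len += ((s % nr) != (first % nr) && (s / nr) != (first / nr)) ? SQ2 : 1.0;
    while (cur != s) {
      int cr = cur % nr, ccol = cur / nr;
      int nxt = -1;
      for (int q = 0; q < 8; ++q) {
        int r2 = cr + dr[q], c2 = ccol + dc[q];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int cand = r2 + c2 * nr;
        if (deg[cand] < 0 || cand == prev) continue;
        nxt = cand;
        break;
      }
      if (nxt < 0) break;
      long long k2 = (cur < nxt) ? (long long)cur * NN + nxt
                                 : (long long)nxt * NN + cur;
      seen.insert(k2);
      len += (cr != (nxt % nr) && ccol != (nxt / nr)) ? SQ2 : 1.0;
      prev = cur;
      cur = nxt;
    }
    ++strut_count;
    total_len += len;
    lens.push_back(len);
  }

  return List::create(
    _["node_count"] = nodes,
    _["endpoint_count"] = endpoints,
    _["isolated_count"] = isolated,
    _["strut_count"] = strut_count,
    _["total_length_px"] = total_len,
    _["strut_lengths_px"] = NumericVector(lens.begin(), lens.end()));
}
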