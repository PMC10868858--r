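#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF = 1000000000;

static inline int code_of(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 3;
  case 'T': case 't': return 4;
  default: return 5;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_encode(std::string s) {
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = code_of(s[i]);
  return out;
}

// Banded global alignment (unit costs) with traceback.  Offsets d = i - j
// are restricted to [min(0,n-m)-band, max(0,n-m)+band]; the DP is exact
// whenever the optimal path stays inside the band, and `edge` reports a
// traceback that touched the band boundary so the caller can widen it.
//
// Work buffers are passed in so batch callers pay no per-read allocation.
// proj[j] (0-based ref column j) receives the read base code aligned to
// that column, or 0 when the column is deleted.
struct AlignWork {
  std::vector<int> prev, cur;
  std::vector<unsigned char> mv;   // 1 diag, 2 horiz (ref del), 3 vert (read ins)
};

static int banded_core(const std::vector<int>& rc, const std::vector<int>& fc,
                       int band, AlignWork& w, std::vector<int>& proj,
                       bool& edge) {
  const int n = (int) rc.size(), m = (int) fc.size();
  const int dlo = std::min(0, n - m) - band;
  const int dhi = std::max(0, n - m) + band;
  const int W = dhi - dlo + 1;
  w.prev.assign(W + 2, INF);
  w.cur.assign(W + 2, INF);
  w.mv.resize((size_t)(m + 1) * W);
  int* prev = w.prev.data() + 1;   // sentinel INF at [-1] and [W]
  int* cur = w.cur.data() + 1;
  unsigned char* mv = w.mv.data();

  for (int k = 0; k < W; ++k) {
    const int i = dlo + k;
    if (i >= 0 && i <= n) {
      prev[k] = i;
      mv[k] = i > 0 ? 3 : 0;
    }
  }
  for (int j = 1; j <= m; ++j) {
    const int cj = fc[j - 1];
    unsigned char* mvj = mv + (size_t) j * W;
    const int klo = std::max(0, -(j + dlo));
    const int khi = std::min(W - 1, n - j - dlo);
    if (klo > 0) cur[klo - 1] = INF;      // guard below the valid range
    for (int k = klo; k <= khi; ++k) {
      const int i = j + dlo + k;
      int best, op;
      if (i > 0) {
        best = prev[k] + ((rc[i - 1] == cj && cj != 5) ? 0 : 1);
        op = 1;
      } else { best = INF; op = 0; }
      const int h = prev[k + 1] + 1;        // ref char deleted
      if (h < best) { best = h; op = 2; }
      const int v = cur[k - 1] + 1;         // read char inserted
      if (v < best) { best = v; op = 3; }
      cur[k] = best;
      mvj[k] = (unsigned char) op;
    }
    if (khi + 1 <= W - 1) cur[khi + 1] = INF;
    std::swap(w.prev, w.cur);
    prev = w.prev.data() + 1;
    cur = w.cur.data() + 1;
  }
  const int kend = n - m - dlo;
  int dist = (kend >= 0 && kend < W) ? prev[kend] : INF;
  edge = dist >= INF;
  proj.assign(m, 0);
  if (dist < INF) {
    int i = n, j = m, k = kend;
    while (i > 0 || j > 0) {
      if ((k == 0 || k == W - 1) && W < n + m + 2) edge = true;
      const unsigned char op = mv[(size_t) j * W + k];
      if (op == 1) { proj[j - 1] = rc[i - 1]; --i; --j; }
      else if (op == 2) { proj[j - 1] = 0; --j; ++k; }
      else if (op == 3) { --i; --k; }
      else break;
    }
  }
  return dist;
}

static int banded_auto(const std::vector<int>& rc, const std::vector<int>& fc,
                       int band, AlignWork& w, std::vector<int>& proj) {
  const int n = (int) rc.size(), m = (int) fc.size();
  bool edge = true;
  int dist = INF;
  while (true) {
    dist = banded_core(rc, fc, band, w, proj, edge);
    if (!edge || band >= std::max(n, m)) break;
    band *= 2;
  }
  return dist;
}

static std::vector<int> encode_vec(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = code_of(s[i]);
  return v;
}

// [[Rcpp::export]]
List cpp_banded_align(std::string read, std::string ref, int band) {
  AlignWork w;
  std::vector<int> proj;
  bool edge;
  std::vector<int> rc = encode_vec(read), fc = encode_vec(ref);
  int dist = banded_core(rc, fc, band, w, proj, edge);
  return List::create(_["dist"] = dist >= INF ? NA_INTEGER : dist,
                      _["proj"] = wrap(proj),
                      _["edge"] = edge);
}

// Score every same-length reference entry of a DB from one projected
// anchor alignment (diff columns are 0-based).
// [[Rcpp::export]]
IntegerVector cpp_project_scores(int anchor_dist, IntegerVector proj,
                                 List diff_idx, List entry_code, List anchor_code) {
  const int E = diff_idx.size();
  IntegerVector out(E);
  for (int e = 0; e < E; ++e) {
    IntegerVector idx = diff_idx[e], ec = entry_code[e], ac = anchor_code[e];
    int d = anchor_dist;
    for (int t = 0; t < idx.size(); ++t) {
      const int b = proj[idx[t]];
      if (b == 0) continue;                 // gap column: cost 1 either way
      d += (b != ec[t]) - (b != ac[t]);
    }
    out[e] = d;
  }
  return out;
}

// Batch assignment of reads against a same-length reference database:
// one banded anchor alignment per read (automatic band widening), then
// projected scoring of every entry at its divergence columns from the
// anchor.  Returns, per read, the 1-based index of the closest entry (NA
// when discarded), the best distance, and a reason code (0 assigned, 1
// tie between the two best entries, 2 best distance above
// max_dist_frac * read length).
// [[Rcpp::export]]
List cpp_assign_batch(CharacterVector reads, CharacterVector entries,
                      double max_dist_frac, int band) {
  const int E = entries.size();
  std::vector<std::vector<int>> ecodes(E);
  for (int e = 0; e < E; ++e) ecodes[e] = encode_vec(as<std::string>(entries[e]));
  const std::vector<int>& anchor = ecodes[0];
  std::vector<std::vector<int>> didx(E);
  std::vector<std::vector<int>> dec(E);
  for (int e = 0; e < E; ++e) {
    for (size_t c = 0; c < anchor.size(); ++c) {
      if (ecodes[e][c] != anchor[c]) {
        didx[e].push_back((int) c);
        dec[e].push_back(ecodes[e][c]);
      }
    }
  }
  const int n = reads.size();
  IntegerVector best_entry(n), best_dist(n), reason(n);
  AlignWork w;
  std::vector<int> proj;
  for (int r = 0; r < n; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    std::vector<int> rc = encode_vec(rd);
    const int d_anchor = banded_auto(rc, anchor, band, w, proj);
    int b1 = INF, b2 = INF, be = -1;
    for (int e = 0; e < E; ++e) {
      int d = d_anchor;
      const std::vector<int>& ix = didx[e];
      const std::vector<int>& ec = dec[e];
      for (size_t t = 0; t < ix.size(); ++t) {
        const int b = proj[ix[t]];
        if (b == 0) continue;
        d += (b != ec[t]) - (b != anchor[ix[t]]);
      }
      if (d < b1) { b2 = b1; b1 = d; be = e; }
      else if (d < b2) { b2 = d; }
    }
    if (E > 1 && b1 == b2) {
      best_entry[r] = NA_INTEGER; best_dist[r] = b1; reason[r] = 1;
    } else if (b1 > max_dist_frac * (double) rc.size()) {
      best_entry[r] = NA_INTEGER; best_dist[r] = b1; reason[r] = 2;
    } else {
      best_entry[r] = be + 1; best_dist[r] = b1; reason[r] = 0;
    }
  }
  return List::create(_["entry"] = best_entry, _["dist"] = best_dist,
                      _["reason"] = reason);
}
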