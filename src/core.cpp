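#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cstdlib>
using namespace Rcpp;

// Base codes throughout: A=0, C=1, G=2, T=3 (quaternary digits, leftmost
// character most significant in a k-mer code).

// Rolling k-mer codes of a 0..3 integer sequence; empty vector if the
// sequence is shorter than k.  k is capped at 15 so codes fit in int32.
// [[Rcpp::export]]
IntegerVector cpp_kmer_codes(IntegerVector base, int k) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  int n = base.size();
  int m = n - k + 1;
  if (m <= 0) return IntegerVector(0);
  IntegerVector out(m);
  long long msd = 1;
  for (int j = 0; j < k - 1; ++j) msd *= 4;
  long long code = 0;
  for (int i = 0; i < k; ++i) code = code * 4 + base[i];
  out[0] = (int)code;
  for (int i = 1; i < m; ++i) {
    code = (code - (long long)base[i - 1] * msd) * 4 + base[i + k - 1];
    out[i] = (int)code;
  }
  return out;
}

// Similarity S(i, i+w) of the k-mer frequency vectors of windows
// [i, i+w) and [i+w, i+2w), for every i = 0 .. n-2w, in one linear pass.
// method: 1 = Manhattan (1 - L1/(2w)), 2 = Pearson ((rho+1)/2, 0.5 when a
// profile has zero variance).
// [[Rcpp::export]]
NumericVector cpp_window_sims(IntegerVector base, int k, int w, int method) {
  int n = base.size();
  if (k < 1 || k > 12) stop("k must be in 1..12 for window scans");
  if (w < k) stop("window must be at least k");
  int last = n - 2 * w;
  if (last < 0) return NumericVector(0);
  int nb = 1;
  for (int j = 0; j < k; ++j) nb *= 4;
  IntegerVector kc = cpp_kmer_codes(base, k);
  std::vector<int> f(nb, 0), g(nb, 0);
  int q = w - k + 1;  // k-mers per window
  for (int t = 0; t < q; ++t) { f[kc[t]]++; g[kc[w + t]]++; }
  NumericVector S(last + 1);

  if (method == 1) {
    long long l1 = 0;
    for (int x = 0; x < nb; ++x) l1 += std::abs(f[x] - g[x]);
    S[0] = 1.0 - (double)l1 / (2.0 * w);
    for (int i = 1; i <= last; ++i) {
      int ch[4] = { kc[i - 1], kc[i - 1 + q], kc[i - 1 + w], kc[i - 1 + w + q] };
      int dl[4] = { -1, +1, -1, +1 };
      for (int t = 0; t < 4; ++t) {
        int x = ch[t];
        bool inf = (t < 2);  // first two edits touch f, last two touch g
        l1 -= std::abs(f[x] - g[x]);
        if (inf) f[x] += dl[t]; else g[x] += dl[t];
        l1 += std::abs(f[x] - g[x]);
      }
      S[i] = 1.0 - (double)l1 / (2.0 * w);
    }
  } else if (method == 2) {
    long long sff = 0, sgg = 0, sfg = 0;
    for (int x = 0; x < nb; ++x) {
      sff += (long long)f[x] * f[x];
      sgg += (long long)g[x] * g[x];
      sfg += (long long)f[x] * g[x];
    }
    double N = nb, sf = q, sg = q;
    for (int i = 0; i <= last; ++i) {
      if (i > 0) {
        int ch[4] = { kc[i - 1], kc[i - 1 + q], kc[i - 1 + w], kc[i - 1 + w + q] };
        int dl[4] = { -1, +1, -1, +1 };
        for (int t = 0; t < 4; ++t) {
          int x = ch[t], d = dl[t];
          if (t < 2) {
            sff += (long long)d * (2LL * f[x] + d);
            sfg += (long long)d * g[x];
            f[x] += d;
          } else {
            sgg += (long long)d * (2LL * g[x] + d);
            sfg += (long long)d * f[x];
            g[x] += d;
          }
        }
      }
      double vf = N * (double)sff - sf * sf;
      double vg = N * (double)sgg - sg * sg;
      if (vf <= 0 || vg <= 0) {
        S[i] = 0.5;  // zero-variance profile: "no correlation" midpoint
      } else {
        double rho = (N * (double)sfg - sf * sg) / std::sqrt(vf * vg);
        if (rho > 1) rho = 1; if (rho < -1) rho = -1;
        S[i] = (rho + 1.0) / 2.0;
      }
    }
  } else stop("unknown similarity method");
  return S;
}

// Leftmost-tie local maxima of v within radius w: pk[c] = 1 iff
// v[j] < v[c] for j in [c-w, c-1] and v[j] <= v[c] for j in [c+1, c+w]
// (windows clipped at the ends).  Monotone-deque sliding maximum, O(n).
static std::vector<char> leftmost_peaks(const std::vector<double>& v, int w) {
  int len = (int)v.size();
  std::vector<char> pk(len, 0);
  std::deque<int> dq;  // indices; values non-increasing, earliest-first ties
  int t = 0;
  for (int c = 0; c < len; ++c) {
    int hi = std::min(len - 1, c + w);
    while (t <= hi) {
      while (!dq.empty() && v[dq.back()] < v[t]) dq.pop_back();
      dq.push_back(t);
      ++t;
    }
    while (dq.front() < c - w) dq.pop_front();
    if (dq.front() == c) pk[c] = 1;
  }
  return pk;
}

// Candidate ranges from the boundary statistics of one (k, w) pattern.
// B has length n-3w+1; B[t] = B(i, w) at read position i = w + t.
// E(i, w) = -B(i-w, w) lives at read position i = 2w + t for the same t.
// A start b is a leftmost local maximum of B within radius w with
// B >= theta; the end e is the closest position >= b+w whose E locally
// maximizes within radius w and also reaches theta (the floor applies to
// both boundary statistics symmetrically, so in-repeat fluctuations of E
// cannot terminate a range early).  After emitting a range the scan
// resumes at e.  Returns a matrix with columns b, e, peak_b, peak_e.
// [[Rcpp::export]]
NumericMatrix cpp_detect_ranges(NumericVector B, int w, double theta) {
  int L = B.size();
  std::vector<double> Bv(B.begin(), B.end()), Ev(L);
  for (int t = 0; t < L; ++t) Ev[t] = -Bv[t];
  std::vector<char> pkB = leftmost_peaks(Bv, w);
  std::vector<char> pkE = leftmost_peaks(Ev, w);

  std::vector<double> out;
  int t = 0;
  while (t < L) {
    if (pkB[t] && Bv[t] >= theta) {
      int b = w + t;
      int e = -1; double pe = 0;
      // e = 2w + te >= b + w = 2w + t holds for every te >= t
      int te_hit = -1;
      for (int te = t; te < L; ++te) {
        if (pkE[te] && Ev[te] >= theta) { e = 2 * w + te; pe = Ev[te];
                                          te_hit = te; break; }
      }
      if (e >= 0) {
        // a weak peak just left of the true boundary can claim the
        // range; move b to the strongest B inside [b, e - w] so the
        // start is the best boundary of the interval it spans
        int tb = t;
        for (int ix = t + 1; ix <= te_hit && ix < L; ++ix) {
          if (pkB[ix] && Bv[ix] > Bv[tb]) tb = ix;
        }
        b = w + tb;
        out.push_back(b); out.push_back(e);
        out.push_back(Bv[tb]); out.push_back(pe);
        t = e - w;  // resume the b-scan at position e
        continue;
      }
    }
    ++t;
  }
  int nr = (int)out.size() / 4;
  NumericMatrix res(nr, 4);
  for (int r = 0; r < nr; ++r)
    for (int cix = 0; cix < 4; ++cix) res(r, cix) = out[4 * r + cix];
  return res;
}

// Wraparound dynamic programming: align region r against the tandem
// extensions of unit u - any substring of the infinite repetition of u -
// with unit cost 1 for substitution/insertion/deletion.  Both the start
// and the end phase are free (first row D[0][j] = 0; delta = min over
// the last row), so the score is invariant under rotation of the unit:
// the cycle a de Bruijn traversal spells has no canonical start, and an
// anchored first row would charge up to |u| for a phase offset that
// carries no information.
// Returns delta, prefix_delta[i] = delta(u, r[0..i]) for every prefix, and
// when full = TRUE also a traceback summary: per-unit-position column
// counts (rows A,C,G,T,del,insA,insC,insG,insT), copies, matches, columns.
// [[Rcpp::export]]
List cpp_wraparound(IntegerVector u, IntegerVector r, bool full) {
  int m = u.size(), n = r.size();
  if (m < 1) stop("empty unit");
  if (full && (double)(n + 1) * m > 2.6e8)
    stop("alignment matrix too large for traceback; align a subrange");

  std::vector<int> prev(m, 0), cur(m);
  std::vector<int> D;
  if (full) D.resize((size_t)(n + 1) * m, 0);
  IntegerVector prefix_delta(n + 1);
  prefix_delta[0] = 0;

  for (int i = 1; i <= n; ++i) {
    int rc = r[i - 1];
    for (int j = 0; j < m; ++j) {
      int pj = (j == 0) ? m - 1 : j - 1;
      int best = prev[pj] + (rc != u[pj] ? 1 : 0);
      int up = prev[j] + 1;
      if (up < best) best = up;
      if (j > 0) { int dl = cur[j - 1] + 1; if (dl < best) best = dl; }
      cur[j] = best;
    }
    // second pass: deletion runs that wrap across the unit boundary once
    { int dl = cur[m - 1] + 1; if (dl < cur[0]) cur[0] = dl; }
    for (int j = 1; j < m; ++j) {
      int dl = cur[j - 1] + 1; if (dl < cur[j]) cur[j] = dl;
    }
    int mn = cur[0];
    for (int j = 1; j < m; ++j) if (cur[j] < mn) mn = cur[j];
    prefix_delta[i] = mn;
    if (full) {
      int* row = &D[(size_t)i * m];
      for (int j = 0; j < m; ++j) row[j] = cur[j];
    }
    std::swap(prev, cur);
  }
  int delta = prefix_delta[n];

  List out = List::create(_["delta"] = delta,
                          _["prefix_delta"] = prefix_delta);
  if (!full) return out;

  // traceback on the stored matrix (greedy over the Bellman equalities;
  // preference: matching diagonal, mismatching diagonal, deletion, insertion)
  IntegerMatrix cc(9, m);
  int i = n, j = 0;
  {
    const int* row = &D[(size_t)n * m];
    for (int t = 1; t < m; ++t) if (row[t] < row[j]) j = t;
  }
  long long unit_steps = 0, matches = 0, cols = 0;
  while (i > 0) {
    const int* row = &D[(size_t)i * m];
    const int* rup = &D[(size_t)(i - 1) * m];
    int pj = (j == 0) ? m - 1 : j - 1;
    int rc = r[i - 1];
    int diag = rup[pj] + (rc != u[pj] ? 1 : 0);
    if (row[j] == diag && rc == u[pj]) {
      cc(rc, pj)++; matches++; cols++; unit_steps++; --i; j = pj;
    } else if (row[j] == diag) {
      cc(rc, pj)++; cols++; unit_steps++; --i; j = pj;  // substitution
    } else if (row[j] == row[pj] + 1) {
      cc(4, pj)++; cols++; unit_steps++; j = pj;        // unit char deleted
    } else {
      cc(5 + rc, pj)++; cols++; --i;                    // inserted after pj
    }
  }
  out["col_counts"] = cc;
  out["copies"] = (double)unit_steps / m;
  out["matches"] = (double)matches;
  out["columns"] = (double)cols;
  return out;
}

// Length of the longest common subsequence of two code vectors.
// [[Rcpp::export]]
int cpp_lcs(IntegerVector a, IntegerVector b) {
  int n = a.size(), mm = b.size();
  std::vector<int> prev(mm + 1, 0), cur(mm + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= mm; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[mm];
}

// Plain Levenshtein distance of two code vectors (unit costs).
// [[Rcpp::export]]
int cpp_edit(IntegerVector a, IntegerVector b) {
  int n = a.size(), mm = b.size();
  std::vector<int> prev(mm + 1), cur(mm + 1);
  for (int j = 0; j <= mm; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= mm; ++j) {
      int best = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[mm];
}

// Greedy heaviest-cycle search in the k-mer de Bruijn graph given by the
// sorted unique k-mer codes and their counts.  From kappa, frontiers
// next^h(V) are expanded (successors of maximum frequency over the whole
// frontier) until the frontier is empty (failure), a singleton, or contains
// kappa.  Paths through a multi-step frontier are reconstructed by parent
// pointers, preferring the predecessor of maximal frequency (ties: smallest
// code).  forward = false traverses edges backwards; the caller reverses
// the spelled labels.  Returns found flag, unit base codes (in traversal
// order), node codes on the cycle, and the cycle weight.
// [[Rcpp::export]]
List cpp_greedy_cycle(IntegerVector codes, IntegerVector counts, int k,
                      int kappa, bool forward, int max_len, int max_steps) {
  int nn = codes.size();
  long long pk1 = 1;
  for (int j = 0; j < k - 1; ++j) pk1 *= 4;

  auto freq_of = [&](int code) {
    int lo = 0, hi = nn - 1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (codes[mid] == code) return counts[mid];
      if (codes[mid] < code) lo = mid + 1; else hi = mid - 1;
    }
    return 0;
  };

  struct Node { int code; int parent; int label; };
  std::vector<int> unit_labels;
  std::vector<int> cyc_nodes;
  double weight = freq_of(kappa);
  cyc_nodes.push_back(kappa);

  int v = kappa;
  long long total_edges = 0;
  bool closed = false;
  while (!closed) {
    // frontier expansion from {v}
    std::vector<std::vector<Node> > levels;
    levels.push_back(std::vector<Node>(1));
    levels[0][0].code = v; levels[0][0].parent = -1; levels[0][0].label = -1;
    int z_level = -1, z_idx = -1;
    for (int h = 1; ; ++h) {
      if (h > max_steps) return List::create(_["found"] = false);
      const std::vector<Node>& cu = levels[h - 1];
      // successors of every frontier node, keep only max frequency
      int bestf = 0;
      std::vector<Node> nxt;
      for (size_t t = 0; t < cu.size(); ++t) {
        int vc = cu[t].code;
        for (int a = 0; a < 4; ++a) {
          int z = forward ? (int)(((long long)vc % pk1) * 4 + a)
                          : (int)((long long)a * pk1 + vc / 4);
          int fz = freq_of(z);
          if (fz <= 0) continue;
          // edge label: appended char (forward) / removed leading char info
          int lab = forward ? a : (vc & 3);  // backward: last char of child vc
          if (fz > bestf) { bestf = fz; nxt.clear(); }
          if (fz == bestf) {
            Node nd; nd.code = z; nd.parent = (int)t; nd.label = lab;
            nxt.push_back(nd);
          }
        }
      }
      if (nxt.empty()) return List::create(_["found"] = false);
      // deduplicate nodes, keeping the best parent (max freq, then smallest
      // parent code)
      std::vector<Node> ded;
      for (size_t t = 0; t < nxt.size(); ++t) {
        bool seen = false;
        for (size_t s = 0; s < ded.size(); ++s) {
          if (ded[s].code == nxt[t].code) {
            seen = true;
            int fa = freq_of(cu[ded[s].parent].code);
            int fb = freq_of(cu[nxt[t].parent].code);
            if (fb > fa || (fb == fa &&
                cu[nxt[t].parent].code < cu[ded[s].parent].code))
              ded[s] = nxt[t];
            break;
          }
        }
        if (!seen) ded.push_back(nxt[t]);
      }
      levels.push_back(ded);
      // stop: kappa in set, or singleton
      for (size_t t = 0; t < ded.size(); ++t)
        if (ded[t].code == kappa) { z_level = h; z_idx = (int)t; break; }
      if (z_level < 0 && ded.size() == 1) { z_level = h; z_idx = 0; }
      if (z_level >= 0) break;
    }
    // reconstruct the h-edge path from v to z
    std::vector<int> labs(z_level), nods(z_level);
    int idx = z_idx;
    for (int h = z_level; h >= 1; --h) {
      labs[h - 1] = levels[h][idx].label;
      nods[h - 1] = levels[h][idx].code;
      idx = levels[h][idx].parent;
    }
    for (int h = 0; h < z_level; ++h) {
      unit_labels.push_back(labs[h]);
      if (nods[h] != kappa) {
        cyc_nodes.push_back(nods[h]);
        weight += freq_of(nods[h]);
      }
    }
    total_edges += z_level;
    if ((int)total_edges > max_len) return List::create(_["found"] = false);
    v = levels[z_level][z_idx].code;
    if (v == kappa) closed = true;
  }
  return List::create(_["found"] = true,
                      _["labels"] = wrap(unit_labels),
                      _["nodes"] = wrap(cyc_nodes),
                      _["weight"] = weight);
}
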