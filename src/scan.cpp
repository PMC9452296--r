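// Off-target site enumeration under a mismatch + bulge penalty budget.
//
// Two independent algorithms over the same site model:
//   * cpp_scan_oriented       - PAM-anchored banded dynamic program (fast path)
//   * cpp_scan_brute_oriented - exhaustive enumeration of every alignment
//                               shape at every window start (reference path)
//
// Shared site model (documented in the methods vignette):
//   - protospacer aligned 5'->3' with the PAM immediately 3' of it;
//   - substitution cost 1; each bulge base costs `bulge_cost`;
//   - bulge runs are internal (flanked by aligned guide bases), each run
//     <= max_bulge_len, separate runs separated by >= 1 aligned base;
//   - any alignment whose target segment or PAM contains a non-ACGT base
//     is ineligible;
//   - per PAM anchor the minimal-penalty alignment is kept
//     (tie-break: fewer bulge bases, then leftmost start).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static inline int base_bits(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    default: return 0; // N and friends: ineligible
  }
}

static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 15;
    default: return -1;
  }
}

struct Hit {
  int start, end, penalty, mm, dnab, rnab;
  std::string ag, at, pam;
};

static DataFrame hits_to_df(const std::vector<Hit>& hits) {
  int n = (int)hits.size();
  IntegerVector start(n), end(n), penalty(n), mm(n), dnab(n), rnab(n);
  CharacterVector ag(n), at(n), pam(n);
  for (int i = 0; i < n; ++i) {
    start[i] = hits[i].start; end[i] = hits[i].end;
    penalty[i] = hits[i].penalty; mm[i] = hits[i].mm;
    dnab[i] = hits[i].dnab; rnab[i] = hits[i].rnab;
    ag[i] = hits[i].ag; at[i] = hits[i].at; pam[i] = hits[i].pam;
  }
  return DataFrame::create(
    _["start"] = start, _["end"] = end, _["penalty"] = penalty,
    _["mismatches"] = mm, _["dna_bulge_bases"] = dnab,
    _["rna_bulge_bases"] = rnab, _["aligned_guide"] = ag,
    _["aligned_target"] = at, _["pam_observed"] = pam,
    _["stringsAsFactors"] = false);
}

static std::vector<int> pam_pattern_bits(const std::string& pam) {
  std::vector<int> bits(pam.size());
  for (size_t i = 0; i < pam.size(); ++i) {
    int b = iupac_bits(pam[i]);
    if (b < 0) stop("invalid IUPAC code in PAM pattern: '%s'", pam.substr(i, 1).c_str());
    bits[i] = b;
  }
  return bits;
}

// pam_ok[p] : PAM pattern matches at 0-based position p (all bases ACGT)
static std::vector<char> pam_ok_vector(const std::string& s, const std::vector<int>& pb) {
  int L = (int)s.size(), k = (int)pb.size();
  std::vector<char> ok(L, 0);
  for (int p = 0; p + k <= L; ++p) {
    bool good = true;
    for (int q = 0; q < k; ++q) {
      int bb = base_bits(s[p + q]);
      if (bb == 0 || !(bb & pb[q])) { good = false; break; }
    }
    ok[p] = good ? 1 : 0;
  }
  return ok;
}

// ---------------------------------------------------------------------------
// Fast path: PAM-anchored banded DP.
//
// Guide indexed from the PAM-proximal (3') end; target consumed leftwards
// from the base just 5' of the PAM. States: 0 = last op aligned (M);
// 1..maxrun = inside an RNA-bulge run (extra guide base) of that length;
// maxrun+1..2*maxrun = inside a DNA-bulge run (extra target base).
// Lexicographic (cost, bulge bases) minimisation; alignments must start and
// end with an aligned pair, so runs are internal by construction.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_scan_oriented(std::string seq, std::string guide, std::string pam,
                            int max_penalty, int bulge_cost, int max_bulge_len) {
  const int m = (int)guide.size();
  const int L = (int)seq.size();
  const int B0 = max_penalty / bulge_cost;            // max total bulge bases
  const int maxrun = std::min(max_bulge_len, B0);
  const int B = std::min(B0, maxrun > 0 ? B0 : 0);
  const int S = 1 + 2 * maxrun;
  const int k = (int)pam.size();
  std::vector<int> pb = pam_pattern_bits(pam);
  std::vector<int> gb(m);
  for (int i = 0; i < m; ++i) {
    gb[i] = base_bits(guide[i]);
    if (gb[i] == 0) stop("protospacer contains a non-ACGT base");
  }
  std::vector<char> pam_ok = pam_ok_vector(seq, pb);

  const int JMAX = m + B;
  const int INF = INT_MAX / 4;
  // flattened [i][j][s]
  auto idx = [&](int i, int j, int s) { return (i * (JMAX + 1) + j) * S + s; };
  std::vector<int> C((m + 1) * (JMAX + 1) * S), BB(C.size());
  std::vector<signed char> P(C.size()); // parent state for M cells

  std::vector<Hit> hits;

  for (int p = 1; p < L; ++p) {
    if (p + k > L || !pam_ok[p]) continue;
    std::fill(C.begin(), C.end(), INF);
    // init pseudo-state: before any op, stored at (0,0) state 0 but gap-open
    // from it is forbidden (checked via i/j > 0 below)
    C[idx(0, 0, 0)] = 0; BB[idx(0, 0, 0)] = 0;
    int jtop = std::min(JMAX, p);
    for (int i = 1; i <= m; ++i) {
      int jlo = std::max(0, i - B), jhi = std::min(i + B, jtop);
      for (int j = jlo; j <= jhi; ++j) {
        // target char for j-th consumed base (leftwards from PAM)
        int tb = base_bits(seq[p - j]); // valid when j >= 1
        // M: aligned pair, from any state at (i-1, j-1)
        if (j >= 1) {
          int sub = (tb == 0) ? INF : ((tb == gb[m - i]) ? 0 : 1);
          if (sub < INF) {
            int bc_ = INF, bb_ = INF; signed char ps = -1;
            if (i - 1 >= 0 && j - 1 >= 0 && std::abs((i - 1) - (j - 1)) <= B) {
              for (int s = 0; s < S; ++s) {
                int c0 = C[idx(i - 1, j - 1, s)];
                if (c0 >= INF) continue;
                int b0 = BB[idx(i - 1, j - 1, s)];
                if (c0 < bc_ || (c0 == bc_ && b0 < bb_)) { bc_ = c0; bb_ = b0; ps = (signed char)s; }
              }
            }
            if (bc_ < INF && bc_ + sub <= max_penalty) {
              int at = idx(i, j, 0);
              C[at] = bc_ + sub; BB[at] = bb_; P[at] = ps;
            }
          }
        }
        // RNA bulge (extra guide base): consumes i only
        for (int r = 1; r <= maxrun; ++r) {
          int from = (r == 1) ? 0 : r - 1;
          // open only after an aligned pair that is a real op (i-1>=1, j>=1)
          if (r == 1 && !(i - 1 >= 1 && j >= 1)) continue;
          if (std::abs((i - 1) - j) > B) continue;
          int c0 = C[idx(i - 1, j, from)];
          if (c0 >= INF) continue;
          if (r == 1 && from == 0 && i - 1 == 0 && j == 0) continue; // init state
          int c1 = c0 + bulge_cost;
          if (c1 > max_penalty) continue;
          int at = idx(i, j, r);
          int b1 = BB[idx(i - 1, j, from)] + 1;
          if (c1 < C[at] || (c1 == C[at] && b1 < BB[at])) { C[at] = c1; BB[at] = b1; }
        }
        // DNA bulge (extra target base): consumes j only
        if (j >= 1 && tb != 0) {
          for (int r = 1; r <= maxrun; ++r) {
            int from = (r == 1) ? maxrun + 0 : maxrun + r - 1;
            if (r == 1) from = 0;
            else from = maxrun + r - 1;
            if (r == 1 && !(i >= 1 && j - 1 >= 1)) continue;
            if (std::abs(i - (j - 1)) > B) continue;
            int c0 = C[idx(i, j - 1, from)];
            if (c0 >= INF) continue;
            int c1 = c0 + bulge_cost;
            if (c1 > max_penalty) continue;
            int at = idx(i, j, maxrun + r);
            int b1 = BB[idx(i, j - 1, from)] + 1;
            if (c1 < C[at] || (c1 == C[at] && b1 < BB[at])) { C[at] = c1; BB[at] = b1; }
          }
        }
      }
    }
    // best end: full guide consumed, last op aligned; prefer
    // (cost, bulges, larger j == leftmost start)
    int bj = -1, bc = INF, bb = INF;
    for (int j = std::max(0, m - B); j <= std::min(m + B, jtop); ++j) {
      int c0 = C[idx(m, j, 0)];
      if (c0 >= INF) continue;
      int b0 = BB[idx(m, j, 0)];
      if (c0 < bc || (c0 == bc && (b0 < bb || (b0 == bb && j > bj)))) {
        bc = c0; bb = b0; bj = j;
      }
    }
    if (bj < 0 || bc > max_penalty) continue;
    // traceback from (m, bj, 0)
    std::string ops; // PAM-proximal -> distal
    int i = m, j = bj, s = 0;
    while (i > 0 || j > 0) {
      if (s == 0) {
        int tb = base_bits(seq[p - j]);
        ops.push_back((tb == gb[m - i]) ? '=' : 'X');
        s = P[idx(i, j, 0)]; --i; --j;
      } else if (s >= 1 && s <= maxrun) {
        ops.push_back('R');
        s = (s == 1) ? 0 : s - 1; --i;
      } else {
        ops.push_back('D');
        int r = s - maxrun;
        s = (r == 1) ? 0 : maxrun + r - 1; --j;
      }
    }
    // traceback starts at the distal (5') end, so ops are already in
    // genome (5'->3') order of the protospacer strand
    Hit h; h.start = p - bj; h.end = p; h.penalty = bc;
    h.mm = 0; h.dnab = 0; h.rnab = 0;
    int gi = 0, t = p - bj;
    for (char o : ops) {
      if (o == '=' || o == 'X') {
        h.ag.push_back(guide[gi]); h.at.push_back((char)toupper(seq[t]));
        if (o == 'X') ++h.mm;
        ++gi; ++t;
      } else if (o == 'R') {
        h.ag.push_back(guide[gi]); h.at.push_back('-'); ++h.rnab; ++gi;
      } else {
        h.ag.push_back('-'); h.at.push_back((char)toupper(seq[t])); ++h.dnab; ++t;
      }
    }
    h.pam = seq.substr(p, k);
    for (auto& c : h.pam) c = (char)toupper(c);
    hits.push_back(h);
  }
  return hits_to_df(hits);
}

// ---------------------------------------------------------------------------
// Reference path: exhaustive alignment-shape enumeration.
//
// A shape is an op string over {M, R, D} beginning and ending with M, with
// gap runs internal, each run <= max_bulge_len, runs separated by >= 1 M,
// and total gap bases bounded by the penalty budget. Every shape is tried
// at every window start on the given orientation.
// ---------------------------------------------------------------------------
static void enum_shapes(int m, int maxrun, int maxgap,
                        std::string& cur, int gi, int gaps, char lastgap, int runlen,
                        std::vector<std::string>& out) {
  if (gi == m) {
    if (!cur.empty() && cur.back() == 'M') out.push_back(cur);
    return;
  }
  // aligned base
  cur.push_back('M');
  enum_shapes(m, maxrun, maxgap, cur, gi + 1, gaps, 'M', 0, out);
  cur.pop_back();
  bool interior = !cur.empty() && gi < m; // a gap needs an M before and after
  if (!interior || gaps >= maxgap) return;
  // extend / open RNA bulge run (consumes guide)
  if ((lastgap == 'R' && runlen < maxrun) || (cur.back() == 'M' && maxrun > 0)) {
    int rl = (lastgap == 'R') ? runlen + 1 : 1;
    if (rl <= maxrun && gi + 1 <= m - 1) { // must leave >= 1 guide base for closing M
      cur.push_back('R');
      enum_shapes(m, maxrun, maxgap, cur, gi + 1, gaps + 1, 'R', rl, out);
      cur.pop_back();
    }
  }
  // extend / open DNA bulge run (consumes target)
  if ((lastgap == 'D' && runlen < maxrun) || (cur.back() == 'M' && maxrun > 0)) {
    int rl = (lastgap == 'D') ? runlen + 1 : 1;
    if (rl <= maxrun) {
      cur.push_back('D');
      enum_shapes(m, maxrun, maxgap, cur, gi, gaps + 1, 'D', rl, out);
      cur.pop_back();
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_scan_brute_oriented(std::string seq, std::string guide, std::string pam,
                                  int max_penalty, int bulge_cost, int max_bulge_len) {
  const int m = (int)guide.size();
  const int L = (int)seq.size();
  const int k = (int)pam.size();
  const int maxgap = max_penalty / bulge_cost;
  const int maxrun = std::min(max_bulge_len, maxgap);
  std::vector<int> pb = pam_pattern_bits(pam);
  std::vector<int> gb(m);
  for (int i = 0; i < m; ++i) {
    gb[i] = base_bits(guide[i]);
    if (gb[i] == 0) stop("protospacer contains a non-ACGT base");
  }
  std::vector<char> pam_ok = pam_ok_vector(seq, pb);
  std::vector<std::string> shapes;
  { std::string cur; enum_shapes(m, maxrun, maxgap, cur, 0, 0, 'M', 0, shapes); }

  std::vector<Hit> hits;
  for (const std::string& sh : shapes) {
    int t = 0, gaps = 0;
    for (char o : sh) { if (o != 'R') ++t; if (o != 'M') ++gaps; }
    int gap_pen = bulge_cost * gaps;
    if (gap_pen > max_penalty) continue;
    for (int st = 0; st + t + k <= L; ++st) {
      if (!pam_ok[st + t]) continue;
      int mm = 0, gi = 0, tj = st;
      bool ok = true;
      for (char o : sh) {
        if (o == 'M') {
          int tb = base_bits(seq[tj]);
          if (tb == 0) { ok = false; break; }
          if (tb != gb[gi]) { ++mm; if (mm + gap_pen > max_penalty) { ok = false; break; } }
          ++gi; ++tj;
        } else if (o == 'R') {
          ++gi;
        } else {
          if (base_bits(seq[tj]) == 0) { ok = false; break; }
          ++tj;
        }
      }
      if (!ok) continue;
      Hit h; h.start = st; h.end = st + t; h.penalty = mm + gap_pen;
      h.mm = mm; h.dnab = 0; h.rnab = 0;
      gi = 0; tj = st;
      for (char o : sh) {
        if (o == 'M') {
          h.ag.push_back(guide[gi]); h.at.push_back((char)toupper(seq[tj])); ++gi; ++tj;
        } else if (o == 'R') {
          h.ag.push_back(guide[gi]); h.at.push_back('-'); ++h.rnab; ++gi;
        } else {
          h.ag.push_back('-'); h.at.push_back((char)toupper(seq[tj])); ++h.dnab; ++tj;
        }
      }
      h.pam = seq.substr(st + t, k);
      for (auto& c : h.pam) c = (char)toupper(c);
      hits.push_back(h);
    }
  }
  return hits_to_df(hits);
}
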