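#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Exact k-mer matches between query and subject (0-based start positions).
// k-mers containing non-ACGT characters are skipped; subject k-mers with
// more than max_occ occurrences are skipped to bound output size.
// [[Rcpp::export]]
IntegerMatrix seed_hits_cpp(std::string q, std::string s, int k,
                            int max_occ = 64) {
  if (k < 2 || k > 15) stop("seed k must be in [2, 15]");
  const uint32_t mask = (1u << (2 * k)) - 1u;
  std::unordered_map<uint32_t, std::vector<int> > idx;
  // index subject
  {
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = code(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }
  }
  std::vector<int> qpos, spos;
  {
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      int c = code(q[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask;
      if (++run >= k) {
        auto it = idx.find(h);
        if (it != idx.end() && (int)it->second.size() <= max_occ) {
          for (int p : it->second) {
            qpos.push_back(i - k + 1);
            spos.push_back(p);
          }
        }
      }
    }
  }
  IntegerMatrix out(qpos.size(), 2);
  for (size_t i = 0; i < qpos.size(); ++i) {
    out(i, 0) = qpos[i];
    out(i, 1) = spos[i];
  }
  return out;
}

// Smith-Waterman local alignment with affine gaps. A gap of length L costs
// gap_open + gap_ext * L (BLAST-style; matches Biostrings' gapOpening /
// gapExtension convention). Returns the single best local alignment with
// 0-based half-open intervals, match count and aligned column count from
// an explicit traceback.
// [[Rcpp::export]]
List affine_local_cpp(std::string q, std::string s, double match = 1.0,
                      double mismatch = -1.0, double gap_open = 10.0,
                      double gap_ext = 10.0) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double NEG = -1e30;
  const double gi = gap_open + gap_ext;  // cost of first gapped position
  if ((double)n * (double)m > 6.4e7)
    stop("alignment problem too large for exact DP");

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  // traceback: tbH 0 stop, 1 diag, 2 from E (gap in subject), 3 from F
  // tbE/tbF: 0 opened from H, 1 extended
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    double F = NEG;
    Hcur[0] = 0.0; Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t)i * (m + 1) + j;
      // E: gap in subject (consume query), vertical
      double e_open = Hprev[j] - gi, e_ext = Eprev[j] - gap_ext;
      double E = (e_open >= e_ext) ? e_open : e_ext;
      tbE[at] = (e_open >= e_ext) ? 0 : 1;
      // F: gap in query (consume subject), horizontal
      double f_open = Hcur[j - 1] - gi, f_ext = F - gap_ext;
      double Fv = (f_open >= f_ext) ? f_open : f_ext;
      tbF[at] = (f_open >= f_ext) ? 0 : 1;
      F = Fv;
      double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + sub;
      double h = 0.0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E > h) { h = E; tb = 2; }
      if (Fv > h) { h = Fv; tb = 3; }
      Hcur[j] = h; Ecur[j] = E; tbH[at] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0);

  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  int matches = 0, cols = 0;
  int qe = bi, se = bj;
  while (true) {
    size_t at = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t tb = tbH[at];
      if (tb == 0) break;
      if (tb == 1) {
        ++cols;
        if (q[i - 1] == s[j - 1]) ++matches;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++cols;
      uint8_t tb = tbE[at];
      --i;
      state = (tb == 0) ? 0 : 1;
    } else {
      ++cols;
      uint8_t tb = tbF[at];
      --j;
      state = (tb == 0) ? 0 : 2;
    }
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = qe,
    _["s_start"] = j, _["s_end"] = se,
    _["matches"] = matches, _["cols"] = cols);
}
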