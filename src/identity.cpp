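// Global (Needleman-Wunsch/Gotoh) alignment identity with affine gaps.
//
// Scoring: match +1, mismatch 0, gap of length L costs open + L * ext
// (end gaps penalized). Identity = matched columns / total alignment
// columns, recovered by traceback. The unknown residue X never matches.
// Scores are kept in two rolling float rows per state; the traceback keeps
// one packed byte per cell (2 bits per state), so the working set stays
// cache-resident for typical protein lengths.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

namespace {

const float NEG_INF = -1e30f;

inline int encode(char c) {
  if (c >= 'A' && c <= 'Z') return c - 'A';
  return -1;
}

struct AlignResult {
  int matches;
  int columns;
};

// states: 0 = M (aligned pair), 1 = GA (gap in b, consume a),
// 2 = GB (gap in a, consume b). tb byte: bits 0-1 tM, 2-3 tA, 4-5 tB.
AlignResult align_pair(const std::vector<int>& a, const std::vector<int>& b,
                       float open, float ext,
                       std::vector<float>& buf, std::vector<unsigned char>& tb) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  const float open_ext = open + ext;
  if ((int)buf.size() < 6 * w) buf.resize(6 * w);
  if ((int)tb.size() < (n + 1) * w) tb.assign((size_t)(n + 1) * w, 0);
  else std::fill(tb.begin(), tb.begin() + (size_t)(n + 1) * w, 0);

  float* Mp = buf.data();            // previous row, state M
  float* Ap = Mp + w;                // previous row, state GA
  float* Bp = Ap + w;                // previous row, state GB
  float* Mc = Bp + w;                // current row
  float* Ac = Mc + w;
  float* Bc = Ac + w;

  Mp[0] = 0.0f; Ap[0] = NEG_INF; Bp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Ap[j] = NEG_INF;
    Bp[j] = -(open + ext * j);
    tb[j] = (unsigned char)(((j == 1) ? 0 : 2) << 4);
  }

  const int xcode = 'X' - 'A';
  for (int i = 1; i <= n; ++i) {
    const int xi = a[i - 1];
    unsigned char* tbrow = tb.data() + (size_t)i * w;
    Mc[0] = NEG_INF; Bc[0] = NEG_INF;
    Ac[0] = -(open + ext * i);
    tbrow[0] = (unsigned char)(((i == 1) ? 0 : 1) << 2);
    for (int j = 1; j <= m; ++j) {
      const float s =
          (xi >= 0 && xi == b[j - 1] && xi != xcode) ? 1.0f : 0.0f;
      // M from diagonal (previous row, j-1)
      float bm = Mp[j - 1];
      unsigned char am = 0;
      if (Ap[j - 1] > bm) { bm = Ap[j - 1]; am = 1; }
      if (Bp[j - 1] > bm) { bm = Bp[j - 1]; am = 2; }
      const float Mv = bm + s;
      // GA from above (previous row, j)
      float ba = Mp[j] - open_ext;
      unsigned char aa = 0;
      const float ga_ext = Ap[j] - ext;
      if (ga_ext > ba) { ba = ga_ext; aa = 1; }
      const float ga_gb = Bp[j] - open_ext;
      if (ga_gb > ba) { ba = ga_gb; aa = 2; }
      // GB from left (current row, j-1)
      float bb = Mc[j - 1] - open_ext;
      unsigned char ab = 0;
      const float gb_ga = Ac[j - 1] - open_ext;
      if (gb_ga > bb) { bb = gb_ga; ab = 1; }
      const float gb_ext = Bc[j - 1] - ext;
      if (gb_ext > bb) { bb = gb_ext; ab = 2; }
      Mc[j] = Mv; Ac[j] = ba; Bc[j] = bb;
      tbrow[j] = (unsigned char)(am | (aa << 2) | (ab << 4));
    }
    std::swap(Mp, Mc); std::swap(Ap, Ac); std::swap(Bp, Bc);
  }

  // best final state (scores now live in the "previous" row pointers)
  int state = 0;
  {
    float best = Mp[m];
    if (Ap[m] > best) { best = Ap[m]; state = 1; }
    if (Bp[m] > best) { state = 2; }
  }
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    ++columns;
    const unsigned char t = tb[(size_t)i * w + j];
    if (state == 0) {
      const int xi = a[i - 1];
      if (xi >= 0 && xi == b[j - 1] && xi != xcode) ++matches;
      state = t & 3;
      --i; --j;
    } else if (state == 1) {
      state = (t >> 2) & 3;
      --i;
    } else {
      state = (t >> 4) & 3;
      --j;
    }
  }
  AlignResult r;
  r.matches = matches;
  r.columns = columns;
  return r;
}

std::vector<int> encode_string(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) v[k] = encode(s[k]);
  return v;
}

}  // namespace

// [[Rcpp::export(name = ".identity_many_cpp")]]
NumericVector identity_many_cpp(std::string query, CharacterVector subjects,
                                double gap_open, double gap_ext) {
  const std::vector<int> q = encode_string(query);
  if (q.empty()) stop("empty query sequence");
  NumericVector out(subjects.size());
  std::vector<float> buf;
  std::vector<unsigned char> tb;
  for (R_xlen_t k = 0; k < subjects.size(); ++k) {
    const std::vector<int> s = encode_string(as<std::string>(subjects[k]));
    if (s.empty()) stop("empty subject sequence");
    AlignResult r = align_pair(q, s, (float)gap_open, (float)gap_ext, buf, tb);
    out[k] = (double)r.matches / (double)r.columns;
  }
  return out;
}
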