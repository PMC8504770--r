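#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global affine-gap pairwise alignment (Gotoh three-state DP).
//
// Scoring: a gap run of length L costs gap_open + L * gap_extend (the open
// penalty is a run-start surcharge; every gapped column also pays extend).
// 'N' is neutral: it scores 0 against any base, never match or mismatch.
// Traceback ties prefer the diagonal, then a gap in the slave (master
// consumed), then a gap in the master, so results are deterministic.
//
// Scores roll over two rows; the traceback stores, per cell, the source
// state of each of the three DP states packed into one byte.

static const float NEG = -1e30f;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string master, std::string slave,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const size_t n = master.size(), m = slave.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("sequences too long for global alignment (%d x %d)",
         (int)n, (int)m);

  const float ma = (float)match, mi = (float)mismatch;
  const float go = (float)gap_open, ge = (float)gap_extend;
  const size_t W = m + 1;

  // state 0 = M (diagonal), 1 = X (gap in slave, master consumed),
  // 2 = Y (gap in master, slave consumed)
  std::vector<float> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  std::vector<uint8_t> trace((n + 1) * W, 0);

  Mp[0] = 0.0f; Xp[0] = NEG; Yp[0] = NEG;
  for (size_t j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = go + ge * (float)j;
    trace[j] = (uint8_t)(2u << 4);       // Y came from Y
  }

  // precompute slave scores per base to skip the char compare in the loop
  std::vector<char> sv(slave.begin(), slave.end());

  for (size_t i = 1; i <= n; ++i) {
    const char ai = master[i - 1];
    const bool aiN = (ai == 'N');
    uint8_t *tr = &trace[i * W];
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = go + ge * (float)i;
    tr[0] = (uint8_t)(1u << 2);          // X came from X
    for (size_t j = 1; j <= m; ++j) {
      // M: diagonal step from best of the three states at (i-1, j-1)
      const char bj = sv[j - 1];
      const float s = (aiN || bj == 'N') ? 0.0f : (ai == bj ? ma : mi);
      float best = Mp[j - 1];
      unsigned srcM = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; srcM = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; srcM = 2; }
      Mc[j] = best + s;
      // X: consume master[i], gap char in slave; from (i-1, j)
      float xb = Mp[j] + go + ge;
      unsigned srcX = 0;
      if (Xp[j] + ge > xb) { xb = Xp[j] + ge; srcX = 1; }
      if (Yp[j] + go + ge > xb) { xb = Yp[j] + go + ge; srcX = 2; }
      Xc[j] = xb;
      // Y: consume slave[j], gap char in master; from (i, j-1)
      float yb = Mc[j - 1] + go + ge;
      unsigned srcY = 0;
      if (Xc[j - 1] + go + ge > yb) { yb = Xc[j - 1] + go + ge; srcY = 1; }
      if (Yc[j - 1] + ge > yb) { yb = Yc[j - 1] + ge; srcY = 2; }
      Yc[j] = yb;
      tr[j] = (uint8_t)(srcM | (srcX << 2) | (srcY << 4));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  unsigned state = 0;
  float score = Mp[m];
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }

  std::string am, as;
  am.reserve(n + m);
  as.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t t = trace[i * W + j];
    if (state == 0 && i > 0 && j > 0) {
      am.push_back(master[i - 1]);
      as.push_back(slave[j - 1]);
      --i; --j;
      state = t & 3u;
    } else if (state == 1 && i > 0) {
      am.push_back(master[i - 1]);
      as.push_back('-');
      --i;
      state = (t >> 2) & 3u;
    } else {                     // state 2 (or forced edge move)
      am.push_back('-');
      as.push_back(slave[j - 1]);
      --j;
      state = (t >> 4) & 3u;
    }
  }
  std::reverse(am.begin(), am.end());
  std::reverse(as.begin(), as.end());

  return List::create(_["score"] = (double)score,
                      _["master"] = am,
                      _["slave"] = as);
}
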