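#include <Rcpp.h>
using namespace Rcpp;

// RNA-RNA local complementarity alignment (Smith-Waterman, affine gaps).
// The query is aligned 5'->3' against the reverse of the target, so aligned
// columns pair antiparallel strands. Pair scores: Watson-Crick = match,
// G:U = wobble, else mismatch; columns falling in the query seed region
// (positions seed_start..seed_end from the 5' end) have their pair score
// multiplied by seed_scale.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1;
  }
}

// 0 = no bond, 1 = Watson-Crick, 2 = G:U wobble
static inline int bond_type(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1; // A:U
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1; // G:C
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 2; // G:U
  return 0;
}

// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string query, std::string target,
                      double match_score, double gu_wobble_score,
                      double mismatch_score, double gap_open,
                      double gap_extend, int seed_start, int seed_end,
                      double seed_scale) {
  const int n = query.size();
  const int m = target.size();

  std::vector<int> q(n), rt(m);
  for (int i = 0; i < n; ++i) {
    q[i] = base_code(query[i]);
    if (q[i] < 0) stop("invalid RNA symbol '%s' in query (expected A/C/G/U)",
                       std::string(1, query[i]));
  }
  // reverse target so that column (i, j) pairs antiparallel positions
  for (int j = 0; j < m; ++j) {
    int c = base_code(target[m - 1 - j]);
    if (c < 0) stop("invalid RNA symbol '%s' in target (expected A/C/G/U)",
                    std::string(1, target[m - 1 - j]));
    rt[j] = c;
  }

  const double NEG = -1e18;
  const int W = m + 1;
  // DP matrices: M = column ends in a pair, X = gap in query (consumes
  // target), Y = gap in target (consumes query)
  std::vector<double> M((n + 1) * W, 0.0), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: predecessor state (0=M,1=X,2=Y,3=start)
  std::vector<unsigned char> pM((n + 1) * W, 3), pX((n + 1) * W, 0),
      pY((n + 1) * W, 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      int bt = bond_type(q[i - 1], rt[j - 1]);
      double s = (bt == 1) ? match_score
                           : (bt == 2) ? gu_wobble_score : mismatch_score;
      if (i >= seed_start && i <= seed_end) s *= seed_scale;

      const int d = (i - 1) * W + (j - 1);
      // a non-positive predecessor means the local alignment starts here
      double from = 0.0; unsigned char ps = 3;
      if (M[d] > from) { from = M[d]; ps = 0; }
      if (X[d] > from) { from = X[d]; ps = 1; }
      if (Y[d] > from) { from = Y[d]; ps = 2; }
      double cand = from + s;
      if (cand <= 0.0) { M[idx] = 0.0; pM[idx] = 3; }
      else { M[idx] = cand; pM[idx] = ps; }

      const int l = i * W + (j - 1);
      double xo = M[l] + gap_open, xe = X[l] + gap_extend;
      if (xo >= xe) { X[idx] = xo; pX[idx] = 0; }
      else { X[idx] = xe; pX[idx] = 1; }

      const int u = (i - 1) * W + j;
      double yo = M[u] + gap_open, ye = Y[u] + gap_extend;
      if (yo >= ye) { Y[idx] = yo; pY[idx] = 0; }
      else { Y[idx] = ye; pY[idx] = 2; }

      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["empty"] = true);
  }

  // traceback from the best pair-ending cell
  std::string aq, ab, at;
  int i = bi, j = bj, state = 0;
  int paired = 0;
  int qe = bi, je = bj, qs = bi, js = bj;
  static const char BASES[] = "ACGU";
  while (true) {
    const int idx = i * W + j;
    if (state == 0) {
      int bt = bond_type(q[i - 1], rt[j - 1]);
      aq.push_back(BASES[q[i - 1]]);
      at.push_back(BASES[rt[j - 1]]);
      ab.push_back(bt == 1 ? '|' : (bt == 2 ? ':' : ' '));
      if (bt > 0) ++paired;
      qs = i; js = j;
      unsigned char ps = pM[idx];
      --i; --j;
      if (ps == 3) break;
      state = ps;
    } else if (state == 1) {
      aq.push_back('-');
      at.push_back(BASES[rt[j - 1]]);
      ab.push_back(' ');
      unsigned char ps = pX[idx];
      --j;
      state = ps;
    } else {
      aq.push_back(BASES[q[i - 1]]);
      at.push_back('-');
      ab.push_back(' ');
      unsigned char ps = pY[idx];
      --i;
      state = ps;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ab.begin(), ab.end());
  std::reverse(at.begin(), at.end());

  // map reversed-target span back to the target's own 5'->3' coordinates
  int t_start = m - je + 1, t_end = m - js + 1;
  return List::create(
      _["score"] = best, _["empty"] = false, _["paired_bases"] = paired,
      _["q_start"] = qs, _["q_end"] = qe, _["t_start"] = t_start,
      _["t_end"] = t_end, _["align_query"] = aq, _["align_bond"] = ab,
      _["align_target"] = at);
}
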