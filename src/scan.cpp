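#include <Rcpp.h>
using namespace Rcpp;

// Alignment engine for the miRNA target-site scanner.
//
// The query (miRNA, 5'->3') is aligned by local Smith-Waterman with affine
// gaps against the *reversed* target, so that query position k faces the
// target base it would pair with in an antiparallel duplex. Pair scoring is
// done in duplex space: Watson-Crick = match, G:U wobble = gu, otherwise
// mismatch. Substitution scores for query positions seed_lo..seed_hi are
// multiplied by seed_w (miranda-style 5' weighting). Scoring works on the
// two bases directly, never on identity in reverse-complement space.

static inline char dna_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// pair class: 2 = WC, 1 = GU wobble, 0 = other
static inline int pair_kind(char q, char t) {
  if (t == dna_comp(q)) return 2;
  if ((q == 'G' && t == 'T') || (q == 'T' && t == 'G')) return 1;
  return 0;
}

// [[Rcpp::export]]
List sw_scan_cpp(std::string query, std::string target_rev,
                 double match, double gu, double mismatch,
                 double gap_open, double gap_ext,
                 int seed_lo, int seed_hi, double seed_w,
                 double s_min) {
  const int m = (int)query.size(), n = (int)target_rev.size();
  const double NEG = -1e18;
  std::vector<double> H((m + 1) * (n + 1), 0.0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) {
    double w = (i >= seed_lo && i <= seed_hi) ? seed_w : 1.0;
    for (int j = 1; j <= n; ++j) {
      int k = pair_kind(query[i - 1], target_rev[j - 1]);
      double s = (k == 2 ? match : (k == 1 ? gu : mismatch)) * w;
      double e = std::max(H[at(i - 1, j)] + gap_open, E[at(i - 1, j)] + gap_ext);
      double f = std::max(H[at(i, j - 1)] + gap_open, F[at(i, j - 1)] + gap_ext);
      double h = H[at(i - 1, j - 1)] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
    }
  }

  // Candidate end cells: score >= s_min and a local maximum of H over the
  // 3x3 neighborhood (prunes the shoulder cells of the same alignment).
  std::vector<std::pair<int, int> > ends;
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      double h = H[at(i, j)];
      if (h < s_min) continue;
      bool best = true;
      for (int di = -1; di <= 1 && best; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii > m || jj > n) continue;
          if (H[at(ii, jj)] > h) { best = false; break; }
        }
      if (best) ends.push_back(std::make_pair(i, j));
    }

  std::vector<double> score_out;
  std::vector<std::string> qa_out, ta_out;
  std::vector<int> qs_out, qe_out, jlo_out, jhi_out;

  for (size_t c = 0; c < ends.size(); ++c) {
    int i = ends[c].first, j = ends[c].second;
    double sc = H[at(i, j)];
    std::string qa, ta;
    int q_end = i, j_hi = j;
    int state = 0;  // 0 = H, 1 = E (gap in target), 2 = F (gap in query)
    while (i > 0 && j > 0) {
      if (state == 0) {
        double h = H[at(i, j)];
        if (h <= 0) break;
        int k = pair_kind(query[i - 1], target_rev[j - 1]);
        double w = (i >= seed_lo && i <= seed_hi) ? seed_w : 1.0;
        double s = (k == 2 ? match : (k == 1 ? gu : mismatch)) * w;
        if (h == H[at(i - 1, j - 1)] + s) {
          qa.push_back(query[i - 1]);
          ta.push_back(target_rev[j - 1]);
          --i; --j;
        } else if (h == E[at(i, j)]) {
          state = 1;
        } else if (h == F[at(i, j)]) {
          state = 2;
        } else break;  // h == 0 start
      } else if (state == 1) {
        qa.push_back(query[i - 1]);
        ta.push_back('-');
        bool open = (E[at(i, j)] == H[at(i - 1, j)] + gap_open);
        --i;
        state = open ? 0 : 1;
      } else {
        qa.push_back('-');
        ta.push_back(target_rev[j - 1]);
        bool open = (F[at(i, j)] == H[at(i, j - 1)] + gap_open);
        --j;
        state = open ? 0 : 2;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
    score_out.push_back(sc);
    qa_out.push_back(qa);
    ta_out.push_back(ta);
    qs_out.push_back(i + 1);
    qe_out.push_back(q_end);
    jlo_out.push_back(j + 1);
    jhi_out.push_back(j_hi);
  }

  return List::create(_["score"] = score_out, _["query_aln"] = qa_out,
                      _["target_aln"] = ta_out, _["q_start"] = qs_out,
                      _["q_end"] = qe_out, _["j_start"] = jlo_out,
                      _["j_end"] = jhi_out);
}

// Maximal complementary runs between sequence `a` and the reverse
// complement `b_rc` of a partner sequence, scanned along every diagonal.
// A position pairs if a[i] == b_rc[j] (Watson-Crick) or, when allow_gu,
// if (a,G / b,U) or (a,U / b,G) -- which in reverse-complement space is
// a=='G' && b_rc=='A', or a=='T' && b_rc=='C'.
// [[Rcpp::export]]
List diag_runs_cpp(std::string a, std::string b_rc, bool allow_gu,
                   int min_len) {
  const int n = (int)a.size(), m = (int)b_rc.size();
  std::vector<int> i_out, j_out, len_out;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i = d < 0 ? -d : 0;      // 0-based in a
    int j = d < 0 ? 0 : d;       // 0-based in b_rc
    int run = 0;
    while (i < n && j < m) {
      char x = a[i], y = b_rc[j];
      bool hit = (x == y && (x == 'A' || x == 'C' || x == 'G' || x == 'T')) ||
                 (allow_gu && ((x == 'G' && y == 'A') || (x == 'T' && y == 'C')));
      if (hit) {
        ++run;
      } else {
        if (run >= min_len) {
          i_out.push_back(i - run + 1);  // 1-based start in a
          j_out.push_back(j - run + 1);  // 1-based start in b_rc
          len_out.push_back(run);
        }
        run = 0;
      }
      ++i; ++j;
    }
    if (run >= min_len) {
      i_out.push_back(i - run + 1);
      j_out.push_back(j - run + 1);
      len_out.push_back(run);
    }
  }
  return List::create(_["a_start"] = i_out, _["b_rc_start"] = j_out,
                      _["len"] = len_out);
}
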