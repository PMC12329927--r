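#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Alignment and string kernels shared by the preprocessing, OTU and
// classification stages. All alignments are global with free (unpenalised)
// end gaps ("overlap" alignment), affine gap costs: a gap of length L costs
// gap_open + L * gap_ext.

static const double NEG = -1e18;

struct AlnStats {
  double score;
  int matches, mismatches, gap_cols, gap_runs, cols;
  int q_from, q_to; // 1-based query positions covered by the end-trimmed region
};

// Compute column statistics over the end-trimmed alignment. Terminal gap
// runs (leading/trailing columns where one strand has a gap) are excluded,
// mirroring mothur's countends=F / free-end-gap convention.
static AlnStats stats_from_alignment(const std::string &qa, const std::string &ra,
                                     double score) {
  int L = qa.size();
  int lo = 0, hi = L - 1;
  while (lo < L && (qa[lo] == '-' || ra[lo] == '-')) lo++;
  while (hi >= 0 && (qa[hi] == '-' || ra[hi] == '-')) hi--;
  AlnStats st;
  st.score = score;
  st.matches = st.mismatches = st.gap_cols = st.gap_runs = st.cols = 0;
  int qpos = 0, q_from = 0, q_to = 0;
  bool in_gap = false;
  for (int c = 0; c < L; c++) {
    if (qa[c] != '-') qpos++;
    if (c < lo || c > hi) continue;
    st.cols++;
    if (qa[c] != '-' && q_from == 0) q_from = qpos;
    if (qa[c] != '-') q_to = qpos;
    if (qa[c] == '-' || ra[c] == '-') {
      st.gap_cols++;
      if (!in_gap) st.gap_runs++;
      in_gap = true;
    } else {
      in_gap = false;
      if (qa[c] == ra[c]) st.matches++; else st.mismatches++;
    }
  }
  st.q_from = q_from;
  st.q_to = q_to;
  return st;
}

// Gotoh alignment with traceback. free_ends=true gives overlap alignment
// (terminal gaps unpenalised and unscored); free_ends=false is standard
// global alignment with affine end-gap penalties. Returns aligned strings
// and score.
static void gotoh(const std::string &a, const std::string &b,
                  double match, double mismatch, double gap_open, double gap_ext,
                  bool free_ends,
                  std::string &aa, std::string &ba, double &best_score) {
  int n = a.size(), m = b.size();
  int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // provenance: 0 = from M, 1 = from X, 2 = from Y, 3 = free end (init)
  std::vector<unsigned char> pM((n + 1) * W, 3), pX((n + 1) * W, 3), pY((n + 1) * W, 3);
  double go = gap_open + gap_ext;
  M[0] = 0.0;
  if (free_ends) {
    for (int i = 1; i <= n; i++) X[i * W] = 0.0; // free leading gap in b
    for (int j = 1; j <= m; j++) Y[j] = 0.0;     // free leading gap in a
  } else {
    for (int i = 1; i <= n; i++) X[i * W] = gap_open + i * gap_ext;
    for (int j = 1; j <= m; j++) Y[j] = gap_open + j * gap_ext;
  }
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      int id = i * W + j, dg = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
          lf = i * W + (j - 1);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      double best = M[dg]; unsigned char pb = 0;
      if (X[dg] > best) { best = X[dg]; pb = 1; }
      if (Y[dg] > best) { best = Y[dg]; pb = 2; }
      if (best > NEG / 2) { M[id] = best + s; pM[id] = pb; }
      // X: gap in b, consume a[i]
      best = M[up] + go; pb = 0;
      if (X[up] + gap_ext > best) { best = X[up] + gap_ext; pb = 1; }
      if (Y[up] + go > best) { best = Y[up] + go; pb = 2; }
      if (X[up] <= NEG / 2 && M[up] <= NEG / 2 && Y[up] <= NEG / 2) best = NEG;
      if (best > NEG / 2) { X[id] = best; pX[id] = pb; }
      // Y: gap in a, consume b[j]
      best = M[lf] + go; pb = 0;
      if (X[lf] + go > best) { best = X[lf] + go; pb = 1; }
      if (Y[lf] + gap_ext > best) { best = Y[lf] + gap_ext; pb = 2; }
      if (X[lf] <= NEG / 2 && M[lf] <= NEG / 2 && Y[lf] <= NEG / 2) best = NEG;
      if (best > NEG / 2) { Y[id] = best; pY[id] = pb; }
    }
  }
  best_score = NEG;
  int bi = n, bj = m; unsigned char bmat = 0;
  if (free_ends) {
    // free trailing gaps: best cell on last row or last column
    for (int j = 0; j <= m; j++) {
      int id = n * W + j;
      double v = M[id]; unsigned char w = 0;
      if (X[id] > v) { v = X[id]; w = 1; }
      if (Y[id] > v) { v = Y[id]; w = 2; }
      if (v > best_score) { best_score = v; bi = n; bj = j; bmat = w; }
    }
    for (int i = 0; i <= n; i++) {
      int id = i * W + m;
      double v = M[id]; unsigned char w = 0;
      if (X[id] > v) { v = X[id]; w = 1; }
      if (Y[id] > v) { v = Y[id]; w = 2; }
      if (v > best_score) { best_score = v; bi = i; bj = m; bmat = w; }
    }
  } else {
    int id = n * W + m;
    best_score = M[id]; bmat = 0;
    if (X[id] > best_score) { best_score = X[id]; bmat = 1; }
    if (Y[id] > best_score) { best_score = Y[id]; bmat = 2; }
  }
  // build alignment back-to-front
  std::string ra, rb;
  // trailing free gaps
  for (int i = n; i > bi; i--) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > bj; j--) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = bi, j = bj; unsigned char mat = bmat;
  while (i > 0 || j > 0) {
    int id = i * W + j;
    if (mat == 0) {
      if (i == 0 && j == 0) break;
      unsigned char p = pM[id];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      i--; j--; mat = p;
      if (i == 0 && j == 0) break;
      if (p == 3) break;
    } else if (mat == 1) {
      if (j == 0) { // free leading gap region
        while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); i--; }
        break;
      }
      unsigned char p = pX[id];
      ra.push_back(a[i - 1]); rb.push_back('-');
      i--; mat = p;
    } else {
      if (i == 0) {
        while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); j--; }
        break;
      }
      unsigned char p = pY[id];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      j--; mat = p;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && mat == 0) { // remaining b as leading free gap
      while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); j--; }
      break;
    }
    if (j == 0 && mat == 0) {
      while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); i--; }
      break;
    }
  }
  aa.assign(ra.rbegin(), ra.rend());
  ba.assign(rb.rbegin(), rb.rend());
}

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match = 2, double mismatch = -3,
                    double gap_open = -5, double gap_ext = -2,
                    bool free_ends = true, bool alignment = false) {
  std::string aa, ba;
  double score;
  gotoh(a, b, match, mismatch, gap_open, gap_ext, free_ends, aa, ba, score);
  AlnStats st = stats_from_alignment(aa, ba, score);
  List out = List::create(
      _["score"] = st.score, _["matches"] = st.matches,
      _["mismatches"] = st.mismatches, _["gap_cols"] = st.gap_cols,
      _["gap_runs"] = st.gap_runs, _["cols"] = st.cols,
      _["q_from"] = st.q_from, _["q_to"] = st.q_to);
  if (alignment) {
    out["aln_a"] = aa;
    out["aln_b"] = ba;
  }
  return out;
}

// Batched query-vs-references alignment; one row of statistics per reference.
// [[Rcpp::export]]
NumericMatrix align_batch_cpp(std::string query, CharacterVector refs,
                              double match = 2, double mismatch = -3,
                              double gap_open = -5, double gap_ext = -2,
                              bool free_ends = true) {
  int nr = refs.size();
  NumericMatrix out(nr, 8);
  colnames(out) = CharacterVector::create("score", "matches", "mismatches",
                                          "gap_cols", "gap_runs", "cols",
                                          "q_from", "q_to");
  for (int r = 0; r < nr; r++) {
    std::string b = as<std::string>(refs[r]);
    std::string aa, ba;
    double score;
    gotoh(query, b, match, mismatch, gap_open, gap_ext, free_ends, aa, ba, score);
    AlnStats st = stats_from_alignment(aa, ba, score);
    out(r, 0) = st.score; out(r, 1) = st.matches; out(r, 2) = st.mismatches;
    out(r, 3) = st.gap_cols; out(r, 4) = st.gap_runs; out(r, 5) = st.cols;
    out(r, 6) = st.q_from; out(r, 7) = st.q_to;
  }
  return out;
}

// Ungapped merge of a forward read and an already reverse-complemented mate.
// The mate is slid along the forward read (shift s >= 0 of its start);
// the best overlap by matches-minus-mismatches wins (ties: smallest shift).
// At overlap mismatches the base with higher quality wins; quality ties give
// 'N'. Returns status "unmerged" when no overlap of at least min_overlap
// attains a positive score with >= min_identity agreement.
// [[Rcpp::export]]
List merge_pair_cpp(std::string fwd, std::string rvc,
                    IntegerVector qf, IntegerVector qr,
                    int min_overlap = 10, double min_identity = 0.9) {
  int lf = fwd.size(), lr = rvc.size();
  int best_s = -1; double best_score = -std::numeric_limits<double>::infinity();
  int best_ov = 0, best_match = 0;
  for (int s = 0; s + min_overlap <= lf; s++) {
    int ov = std::min(lf - s, lr);
    if (ov < min_overlap) break;
    int mm = 0, ma = 0;
    for (int k = 0; k < ov; k++) {
      if (fwd[s + k] == rvc[k]) ma++; else mm++;
    }
    double sc = ma - mm;
    if (sc > best_score) { best_score = sc; best_s = s; best_ov = ov; best_match = ma; }
  }
  if (best_s < 0 || best_score <= 0 ||
      (double)best_match / best_ov < min_identity) {
    return List::create(_["status"] = "unmerged");
  }
  int s = best_s;
  int total = std::max(lf, s + lr);
  std::string merged(total, 'N');
  std::vector<int> mq(total, 0);
  for (int i = 0; i < s; i++) { merged[i] = fwd[i]; mq[i] = qf[i]; }
  for (int k = 0; k < lr; k++) {
    int pos = s + k;
    if (pos >= lf) { merged[pos] = rvc[k]; mq[pos] = qr[k]; continue; }
    // overlap column
    if (fwd[pos] == rvc[k]) {
      merged[pos] = fwd[pos];
      mq[pos] = std::max((int)qf[pos], (int)qr[k]);
    } else if (qf[pos] > qr[k]) {
      merged[pos] = fwd[pos]; mq[pos] = qf[pos];
    } else if (qr[k] > qf[pos]) {
      merged[pos] = rvc[k]; mq[pos] = qr[k];
    } else {
      merged[pos] = 'N'; mq[pos] = 2;
    }
  }
  for (int i = s + lr; i < lf; i++) { merged[i] = fwd[i]; mq[i] = qf[i]; }
  return List::create(_["status"] = "merged", _["seq"] = merged,
                      _["qual"] = wrap(mq), _["shift"] = s,
                      _["overlap"] = best_ov, _["score"] = best_score);
}

// Best ungapped occurrence of a pattern: minimal mismatches, ties leftmost.
// Returns (1-based start, mismatches) or (0, -1) when the text is shorter
// than the pattern.
// [[Rcpp::export]]
IntegerVector find_anchor_cpp(std::string text, std::string pattern) {
  int lt = text.size(), lp = pattern.size();
  if (lt < lp) return IntegerVector::create(0, -1);
  int best_pos = 1, best_mm = lp + 1;
  for (int s = 0; s + lp <= lt; s++) {
    int mm = 0;
    for (int k = 0; k < lp && mm < best_mm; k++)
      if (text[s + k] != pattern[k]) mm++;
    if (mm < best_mm) { best_mm = mm; best_pos = s + 1; }
  }
  return IntegerVector::create(best_pos, best_mm);
}

// Ungapped overlay distance used by pre-clustering: equal lengths give the
// Hamming distance; unequal lengths slide one sequence along the other and
// the unmatched overhang counts toward the difference budget. Returns
// max_diffs + 1 as soon as the budget is exceeded.
// [[Rcpp::export]]
int overlay_diffs_cpp(std::string a, std::string b, int max_diffs = 2) {
  if (a.size() > b.size()) std::swap(a, b);
  int la = a.size(), lb = b.size();
  int cap = max_diffs + 1;
  if (lb - la > max_diffs) return cap;
  int best = cap;
  for (int s = -max_diffs; s <= lb - la + max_diffs; s++) {
    int from = std::max(0, -s);           // index into a
    int to = std::min(la, lb - s);        // exclusive
    if (to <= from) continue;
    int ov = to - from;
    int unmatched = la + lb - 2 * ov;
    if (unmatched >= best || unmatched > max_diffs) continue;
    int d = unmatched;
    for (int k = from; k < to && d < best; k++)
      if (a[k] != b[s + k]) d++;
    if (d < best) best = d;
  }
  return best;
}

// Cumulative positional mismatches of a query against a parent: out[i] is
// the number of mismatching positions among the first i query bases, where
// query positions beyond the parent's end count as mismatches. Used by the
// de novo chimera scan.
// [[Rcpp::export]]
IntegerVector prefix_mismatch_cpp(std::string q, std::string p) {
  int lq = q.size(), lp = p.size();
  IntegerVector out(lq + 1);
  out[0] = 0;
  for (int i = 1; i <= lq; i++)
    out[i] = out[i - 1] + ((i > lp || q[i - 1] != p[i - 1]) ? 1 : 0);
  return out;
}

// Hamming distance for equal-length strings (read-error planting checks).
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming_cpp: unequal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); i++) if (a[i] != b[i]) d++;
  return d;
}
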