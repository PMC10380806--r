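#include <Rcpp.h>
#include <string>
#include <vector>

// Base-pair maximizing nested folding (Nussinov-style dynamic program).
// Watson-Crick plus G:U wobble pairs; minimum hairpin loop of 3 nt
// (paired positions i,j require j - i >= 4). Traceback prefers pairing
// the outermost compatible positions, giving a deterministic structure.

static inline bool can_pair(char a, char b) {
  // sequences arrive normalized to DNA alphabet (U -> T)
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default:  return false; // N never pairs
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
Rcpp::List nussinov_fold(std::string seq) {
  const int n = (int) seq.size();
  std::string db(n, '.');
  if (n == 0)
    return Rcpp::List::create(Rcpp::Named("structure") = db,
                              Rcpp::Named("n_pairs") = 0);
  // dp[i][j]: max pairs in seq[i..j], 0-based inclusive
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i + 1][j];            // i unpaired
      if (dp[i][j - 1] > best) best = dp[i][j - 1];
      if (can_pair(seq[i], seq[j])) {
        int v = (span >= 4 ? dp[i + 1][j - 1] + 1 : 0);
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {
        int v = dp[i][k] + dp[k + 1][j];
        if (v > best) best = v;
      }
      dp[i][j] = best;
    }
  }
  // iterative traceback, outermost pairing first
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 4) continue;
    int v = dp[i][j];
    if (v == 0) continue;
    if (can_pair(seq[i], seq[j]) && v == dp[i + 1][j - 1] + 1) {
      db[i] = '(';
      db[j] = ')';
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (v == dp[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    if (v == dp[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    bool split = false;
    for (int k = i + 1; k < j; ++k) {
      if (dp[i][k] + dp[k + 1][j] == v) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        split = true;
        break;
      }
    }
    if (!split) Rcpp::stop("traceback failure"); // unreachable
  }
  return Rcpp::List::create(Rcpp::Named("structure") = db,
                            Rcpp::Named("n_pairs") = dp[0][n - 1]);
}

// Hamming-style mismatch count between a query and every same-length
// window of a subject string; helper for the brute-force-friendly
// read mapper.
// [[Rcpp::export(name = ".window_mismatches")]]
Rcpp::IntegerVector window_mismatches(std::string query, std::string subject) {
  const int L = (int) query.size();
  const int n = (int) subject.size() - L + 1;
  if (n <= 0) return Rcpp::IntegerVector(0);
  Rcpp::IntegerVector out(n);
  for (int s = 0; s < n; ++s) {
    int mm = 0;
    for (int k = 0; k < L; ++k)
      if (subject[s + k] != query[k]) ++mm;
    out[s] = mm;
  }
  return out;
}
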