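#include <Rcpp.h>
#include <queue>
#include <vector>
#include <string>
using namespace Rcpp;

// DNA alphabet index; -1 for anything outside uppercase ACGT
static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

struct AcNode {
  int next[4];
  int fail;
  std::vector<int> out;  // pattern indices terminating here (incl. via suffix links)
  AcNode() : fail(0) { next[0] = next[1] = next[2] = next[3] = -1; }
};

// Aho-Corasick automaton scan. Reports every (overlapping) occurrence of every
// pattern in every subject as 0-based start positions.
// [[Rcpp::export(name = ".ac_search")]]
List ac_search(CharacterVector patterns, CharacterVector subjects) {
  const int P = patterns.size();
  std::vector<AcNode> trie(1);
  std::vector<int> plen(P);

  for (int p = 0; p < P; ++p) {
    std::string pat = as<std::string>(patterns[p]);
    plen[p] = pat.size();
    if (pat.empty()) stop("empty pattern");
    int node = 0;
    for (char c : pat) {
      int b = base_idx(c);
      if (b < 0) stop("pattern contains a non-ACGT symbol: '%s'", pat.c_str());
      if (trie[node].next[b] < 0) {
        trie[node].next[b] = trie.size();
        trie.push_back(AcNode());
      }
      node = trie[node].next[b];
    }
    trie[node].out.push_back(p);
  }

  // BFS failure links; missing transitions resolved to goto-automaton form
  std::queue<int> q;
  for (int b = 0; b < 4; ++b) {
    int v = trie[0].next[b];
    if (v < 0) { trie[0].next[b] = 0; } else { trie[v].fail = 0; q.push(v); }
  }
  while (!q.empty()) {
    int u = q.front(); q.pop();
    const std::vector<int>& fout = trie[trie[u].fail].out;
    trie[u].out.insert(trie[u].out.end(), fout.begin(), fout.end());
    for (int b = 0; b < 4; ++b) {
      int v = trie[u].next[b];
      if (v < 0) {
        trie[u].next[b] = trie[trie[u].fail].next[b];
      } else {
        trie[v].fail = trie[trie[u].fail].next[b];
        q.push(v);
      }
    }
  }

  std::vector<int> r_pat, r_seq, r_start;
  const int S = subjects.size();
  for (int s = 0; s < S; ++s) {
    std::string txt = as<std::string>(subjects[s]);
    int node = 0;
    for (int i = 0; i < (int)txt.size(); ++i) {
      int b = base_idx(toupper(txt[i]));
      if (b < 0) { node = 0; continue; }  // N or masked-unknown breaks matches
      node = trie[node].next[b];
      for (int p : trie[node].out) {
        r_pat.push_back(p + 1);
        r_seq.push_back(s + 1);
        r_start.push_back(i - plen[p] + 2);  // 1-based start
      }
    }
  }
  return List::create(_["pattern"] = wrap(r_pat),
                      _["subject"] = wrap(r_seq),
                      _["start"] = wrap(r_start));
}

// Best ungapped overlap between two strings over all relative offsets.
// offset o means b[j] is compared with a[j + o]; returns the offset with the
// most matching positions (smallest offset wins ties) plus match/overlap sizes.
// [[Rcpp::export(name = ".best_ungapped_overlap")]]
IntegerVector best_ungapped_overlap(std::string a, std::string b) {
  const int la = a.size(), lb = b.size();
  int best_m = -1, best_o = 0, best_len = 0;
  for (int o = -(lb - 1); o <= la - 1; ++o) {
    int lo = std::max(0, -o), hi = std::min(lb, la - o);  // j range in b
    int m = 0;
    for (int j = lo; j < hi; ++j) if (b[j] == a[j + o]) ++m;
    int len = hi - lo;
    if (m > best_m) { best_m = m; best_o = o; best_len = len; }
  }
  return IntegerVector::create(_["matches"] = best_m,
                               _["offset"] = best_o,
                               _["overlap"] = best_len);
}

// Fractional identity of the best ungapped alignment whose overlap covers at
// least min_cov of the shorter sequence; identity = matches / shorter length.
// [[Rcpp::export(name = ".ungapped_identity")]]
double ungapped_identity(std::string a, std::string b, double min_cov) {
  const int la = a.size(), lb = b.size();
  const int shorter = std::min(la, lb);
  const int min_ov = (int)std::ceil(min_cov * shorter);
  double best = 0.0;
  for (int o = -(lb - 1); o <= la - 1; ++o) {
    int lo = std::max(0, -o), hi = std::min(lb, la - o);
    if (hi - lo < min_ov) continue;
    int m = 0;
    for (int j = lo; j < hi; ++j) if (toupper(b[j]) == toupper(a[j + o])) ++m;
    double id = (double)m / shorter;
    if (id > best) best = id;
  }
  return best;
}
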