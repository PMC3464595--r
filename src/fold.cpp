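#include <Rcpp.h>
#include "energy.h"

using namespace Rcpp;
using namespace srnabud;

// Minimum-free-energy folding by a Zuker-style dynamic program over the
// reduced nearest-neighbor model in energy.h.  Deterministic traceback:
// candidates are re-examined in a fixed order and the first that attains
// the stored minimum is taken.

namespace {

struct Fold {
  const std::vector<int>& s;
  bool gu;
  int n;
  std::vector<std::vector<int>> V, WM;
  std::vector<int> W;

  Fold(const std::vector<int>& seq, bool allow_gu)
      : s(seq), gu(allow_gu), n((int)seq.size()),
        V(n, std::vector<int>(n, INF_E)),
        WM(n, std::vector<int>(n, INF_E)),
        W(n, 0) {}

  bool pairable(int i, int j) const {
    return j - i - 1 >= MIN_HAIRPIN && pair_type(s[i], s[j], gu) >= 0;
  }

  int v_at(int i, int j) const { return (i < 0 || j >= n || i >= j) ? INF_E : V[i][j]; }
  int wm_at(int i, int j) const { return (i > j) ? INF_E : WM[i][j]; }

  int multi_closed(int i, int j) {
    // multiloop closed by (i,j): >= 2 branches inside (i+1, j-1)
    int best = INF_E;
    for (int m = i + 2; m <= j - 2; ++m) {
      int a = wm_at(i + 1, m), b = wm_at(m + 1, j - 1);
      if (a < INF_E && b < INF_E && a + b + ML_A + ML_B < best)
        best = a + b + ML_A + ML_B;
    }
    return best;
  }

  void fill() {
    for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // --- V ---
        if (pairable(i, j)) {
          int best = hairpin_energy(j - i - 1);
          int pt_out = pair_type(s[i], s[j], gu);
          for (int k = i + 1; k < j - 1 && k - i - 1 <= MAX_INTERIOR; ++k) {
            for (int l = j - 1; l > k; --l) {
              int sz = (k - i - 1) + (j - l - 1);
              if (sz > MAX_INTERIOR) break;
              if (V[k][l] >= INF_E) continue;
              int cost = (sz == 0)
                ? STACK[pt_out][pair_type(s[k], s[l], gu)]
                : interior_energy(sz);
              if (V[k][l] + cost < best) best = V[k][l] + cost;
            }
          }
          int ml = multi_closed(i, j);
          if (ml < best) best = ml;
          V[i][j] = best;
        }
        // --- WM ---
        int wbest = INF_E;
        if (V[i][j] < INF_E) wbest = V[i][j] + ML_B;
        if (wm_at(i + 1, j) < INF_E) wbest = std::min(wbest, WM[i + 1][j] + ML_C);
        if (wm_at(i, j - 1) < INF_E) wbest = std::min(wbest, WM[i][j - 1] + ML_C);
        for (int m = i; m < j; ++m) {
          int a = wm_at(i, m), b = wm_at(m + 1, j);
          if (a < INF_E && b < INF_E) wbest = std::min(wbest, a + b);
        }
        WM[i][j] = wbest;
      }
    }
    // single bases / tiny spans for WM: a lone unpaired base cannot host a
    // branch, keep INF; spans below MIN_HAIRPIN+1 were never filled above.
    for (int j = 0; j < n; ++j) {
      int best = (j > 0) ? W[j - 1] : 0;
      for (int i = 0; i <= j; ++i) {
        if (V[i][j] >= INF_E) continue;
        int left = (i > 0) ? W[i - 1] : 0;
        if (left + V[i][j] < best) best = left + V[i][j];
      }
      W[j] = best;
    }
  }

  void trace_v(int i, int j, std::vector<int>& partner) {
    partner[i] = j; partner[j] = i;
    int target = V[i][j];
    if (target == hairpin_energy(j - i - 1)) return;
    int pt_out = pair_type(s[i], s[j], gu);
    for (int k = i + 1; k < j - 1 && k - i - 1 <= MAX_INTERIOR; ++k) {
      for (int l = j - 1; l > k; --l) {
        int sz = (k - i - 1) + (j - l - 1);
        if (sz > MAX_INTERIOR) break;
        if (V[k][l] >= INF_E) continue;
        int cost = (sz == 0)
          ? STACK[pt_out][pair_type(s[k], s[l], gu)]
          : interior_energy(sz);
        if (V[k][l] + cost == target) { trace_v(k, l, partner); return; }
      }
    }
    for (int m = i + 2; m <= j - 2; ++m) {
      int a = wm_at(i + 1, m), b = wm_at(m + 1, j - 1);
      if (a < INF_E && b < INF_E && a + b + ML_A + ML_B == target) {
        trace_wm(i + 1, m, partner);
        trace_wm(m + 1, j - 1, partner);
        return;
      }
    }
    Rcpp::stop("internal error: traceback failed in V");
  }

  void trace_wm(int i, int j, std::vector<int>& partner) {
    int target = WM[i][j];
    if (V[i][j] < INF_E && V[i][j] + ML_B == target) { trace_v(i, j, partner); return; }
    if (wm_at(i + 1, j) < INF_E && WM[i + 1][j] + ML_C == target) { trace_wm(i + 1, j, partner); return; }
    if (wm_at(i, j - 1) < INF_E && WM[i][j - 1] + ML_C == target) { trace_wm(i, j - 1, partner); return; }
    for (int m = i; m < j; ++m) {
      int a = wm_at(i, m), b = wm_at(m + 1, j);
      if (a < INF_E && b < INF_E && a + b == target) {
        trace_wm(i, m, partner); trace_wm(m + 1, j, partner); return;
      }
    }
    Rcpp::stop("internal error: traceback failed in WM");
  }

  std::vector<int> trace() {
    std::vector<int> partner(n, -1);
    int j = n - 1;
    while (j >= 0) {
      if (j == 0 || W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j; ++i) {
        if (V[i][j] >= INF_E) continue;
        int left = (i > 0) ? W[i - 1] : 0;
        if (left + V[i][j] == W[j]) {
          trace_v(i, j, partner);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) { --j; }
    }
    return partner;
  }
};

std::vector<int> encode(const std::string& seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': case 'a': s[i] = 0; break;
      case 'C': case 'c': s[i] = 1; break;
      case 'G': case 'g': s[i] = 2; break;
      case 'U': case 'u': case 'T': case 't': s[i] = 3; break;
      default: Rcpp::stop("fold: sequence contains a non-ACGTU character");
    }
  }
  return s;
}

} // namespace

// [[Rcpp::export]]
List fold_cpp(std::string seq, bool allow_gu) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  Fold f(s, allow_gu);
  f.fill();
  int mfe = (n > 0) ? f.W[n - 1] : 0;
  std::vector<int> partner = f.trace();
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) { db[i] = '('; db[partner[i]] = ')'; }
  }
  // audit: traceback energy must reproduce the DP minimum
  int check = structure_energy(s, partner, allow_gu);
  if (check != mfe) Rcpp::stop("internal error: traceback energy mismatch");
  return List::create(_["structure"] = db,
                      _["mfe"] = mfe / 100.0,
                      _["pairs"] = IntegerVector(partner.begin(), partner.end()));
}

// Exhaustive enumeration oracle: visits every nested structure (hairpin
// loops >= MIN_HAIRPIN) and scores it by full loop decomposition.
// Independent of the DP above; shares only the parameter tables.

namespace {

struct Brute {
  const std::vector<int>& s;
  bool gu;
  int best;
  std::vector<int> best_partner;
  std::vector<int> partner;

  Brute(const std::vector<int>& seq, bool allow_gu)
      : s(seq), gu(allow_gu), best(0),
        best_partner(seq.size(), -1), partner(seq.size(), -1) {}

  void evaluate() {
    int e = structure_energy(s, partner, gu);
    if (e < best) { best = e; best_partner = partner; }
  }

  // intervals still to be decided, processed depth-first
  void gen(std::vector<std::pair<int,int>>& todo) {
    if (todo.empty()) { evaluate(); return; }
    std::pair<int,int> iv = todo.back();
    int i = iv.first, j = iv.second;
    if (i >= j) { todo.pop_back(); gen(todo); todo.push_back(iv); return; }
    // i unpaired
    todo.back().first = i + 1;
    gen(todo);
    todo.back() = iv;
    // i paired with k
    for (int k = i + MIN_HAIRPIN + 1; k <= j; ++k) {
      if (pair_type(s[i], s[k], gu) < 0) continue;
      partner[i] = k; partner[k] = i;
      todo.back() = std::make_pair(k + 1, j);
      todo.push_back(std::make_pair(i + 1, k - 1));
      gen(todo);
      todo.pop_back();
      todo.back() = iv;
      partner[i] = -1; partner[k] = -1;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List brute_fold_cpp(std::string seq, bool allow_gu) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  if (n > 26) Rcpp::stop("exhaustive enumeration is limited to sequences of at most 26 nt");
  Brute b(s, allow_gu);
  std::vector<std::pair<int,int>> todo;
  todo.push_back(std::make_pair(0, n - 1));
  b.gen(todo);
  std::string db(n, '.');
  for (int i = 0; i < n; ++i)
    if (b.best_partner[i] > i) { db[i] = '('; db[b.best_partner[i]] = ')'; }
  return List::create(_["structure"] = db, _["mfe"] = b.best / 100.0);
}
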