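// Brute-force enumeration of all nested RNA secondary structures of a short
// sequence, scoring each complete structure with the reduced nearest-neighbor
// model (stacks + hairpin-loop initiation + terminal AU/GU penalty).  This is
// the oracle route: it shares only the parameter tables with the R-side
// designed-fold evaluation, not the code path.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct Enumerator {
  const std::vector<int>& seq;       // base codes 0..3 (A,C,G,U)
  const IntegerMatrix& pairidx;      // 4x4 -> pair type 1..6, 0 = unpairable
  const NumericMatrix& stack;        // 6x6 kcal/mol
  const NumericVector& loop_init;    // loop_init[size-1], NA for size < 3
  double au_end;
  int n;

  std::vector<int> mate;             // -1 unpaired, else partner index
  std::vector<int> limits;           // closing positions of open pairs

  double best_dg;
  int best_pairs;
  std::string best_db;
  double n_structures;

  Enumerator(const std::vector<int>& s, const IntegerMatrix& pi,
             const NumericMatrix& st, const NumericVector& li, double au)
      : seq(s), pairidx(pi), stack(st), loop_init(li), au_end(au),
        n((int)s.size()), mate(s.size(), -1),
        best_dg(0.0), best_pairs(0),
        best_db(std::string(s.size(), '.')), n_structures(0.0) {}

  inline bool is_au_gu(int pt) const { return pt != 3 && pt != 4; } // GC=3,CG=4

  void evaluate() {
    n_structures += 1.0;
    double e = 0.0;
    int npairs = 0;
    for (int i = 0; i < n; ++i) {
      int j = mate[i];
      if (j <= i) continue;
      ++npairs;
      int pt = pairidx(seq[i], seq[j]);
      bool inner_stacked = mate[i + 1] == j - 1;
      if (inner_stacked) {
        int pt_in = pairidx(seq[i + 1], seq[j - 1]);
        e += stack(pt - 1, pt_in - 1);
      }
      bool hairpin = true;
      for (int k = i + 1; k < j; ++k)
        if (mate[k] != -1) { hairpin = false; break; }
      if (hairpin) e += loop_init[j - i - 2]; // size j-i-1, index size-1
      if (is_au_gu(pt)) {
        bool outer_term = (i == 0) || (j == n - 1) ||
                          (mate[i - 1] != j + 1);
        if (outer_term) e += au_end;
        if (!inner_stacked) e += au_end;
      }
    }
    if (npairs == 0) return; // open chain is the 0 reference, already seeded
    bool better = false, tie = false;
    if (e < best_dg - 1e-9) better = true;
    else if (e <= best_dg + 1e-9) {
      if (npairs < best_pairs) better = true;
      else if (npairs == best_pairs) tie = true;
    }
    if (!better && !tie) return;
    std::string db(n, '.');
    for (int i = 0; i < n; ++i)
      if (mate[i] > i) { db[i] = '('; db[mate[i]] = ')'; }
    if (better || db < best_db) {
      best_dg = std::min(e, best_dg);
      if (better) best_dg = e;
      best_pairs = npairs;
      best_db = db;
    }
  }

  void rec(int pos) {
    if (pos == n) { evaluate(); return; }
    if (!limits.empty() && pos == limits.back()) {
      // closing base of an open pair: already assigned, step over it
      int saved = limits.back();
      limits.pop_back();
      rec(pos + 1);
      limits.push_back(saved);
      return;
    }
    // option 1: leave pos unpaired
    rec(pos + 1);
    // option 2: pair pos with j inside the innermost enclosing interval
    int lim = limits.empty() ? n : limits.back();
    for (int j = pos + 4; j < lim; ++j) {
      if (pairidx(seq[pos], seq[j]) == 0) continue;
      mate[pos] = j; mate[j] = pos;
      limits.push_back(j);
      rec(pos + 1);
      limits.pop_back();
      mate[pos] = -1; mate[j] = -1;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List enum_mfe_cpp(IntegerVector seq_codes, IntegerMatrix pairidx,
                  NumericMatrix stack, NumericVector loop_init,
                  double au_end) {
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  Enumerator en(s, pairidx, stack, loop_init, au_end);
  if (en.n > 0) en.rec(0);
  else en.n_structures = 1.0;
  return List::create(_["structure"] = en.best_db,
                      _["dg"] = en.best_dg,
                      _["n_structures"] = en.n_structures);
}
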