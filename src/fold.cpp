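// Minimum-free-energy RNA secondary structure prediction over a nearest-
// neighbour energy model: stacking energies for adjacent base pairs plus
// tabulated hairpin / bulge / internal-loop penalties and an affine
// multiloop cost. Energies are handled as integer tenths of kcal/mol so the
// dynamic program and the exhaustive enumeration reference agree exactly.
//
// Parameter table version: mirseeker-nn-1.0 (Turner-style magnitudes,
// no terminal-AU or dangle terms; interior/bulge loops capped at 30 nt).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const int INF = 100000000;
static const int MIN_HAIRPIN = 3;     // smallest terminal loop, nt
static const int MAX_INTERIOR = 30;   // largest bulge/internal loop, nt
static const int ML_CLOSE = 34;      // multiloop closing penalty, 0.1 kcal/mol
static const int ML_BRANCH = 4;      // per-helix multiloop penalty

// base codes: A=0 C=1 G=2 U=3, anything else 4 (unpairable)
static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default:  return 4;
  }
}

// pair codes: CG=0 GC=1 GU=2 UG=3 AU=4 UA=5, -1 if not pairable
static inline int pairCode(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

// stack[outer][inner], outer pair (i,j), inner pair (i+1,j-1); 0.1 kcal/mol
static const int STACK[6][6] = {
  /* CG */ { -33, -24, -14, -21, -21, -21 },
  /* GC */ { -34, -33, -15, -25, -24, -22 },
  /* GU */ { -25, -21,  -5,  13, -13, -14 },
  /* UG */ { -15, -14,   3,  -5, -10,  -6 },
  /* AU */ { -22, -21,  -6, -14,  -9, -11 },
  /* UA */ { -24, -21, -10, -13, -13,  -9 },
};

// Jacobson-Stockmayer extrapolation increment: 1.75 * RT * ln(n/ref)
static inline int jsExtrap(int base, int n, int ref) {
  return base + (int) std::lround(10.78 * std::log((double) n / ref));
}

static inline int hairpinE(int n) {
  static const int H[] = { 54, 56, 57, 54, 60, 55, 64 }; // sizes 3..9
  if (n < MIN_HAIRPIN) return INF;
  if (n <= 9) return H[n - 3];
  return jsExtrap(64, n, 9);
}

static inline int bulgeE(int n) {
  static const int B[] = { 38, 28, 32, 36, 40, 44 }; // sizes 1..6
  if (n < 1 || n > MAX_INTERIOR) return INF;
  if (n <= 6) return B[n - 1];
  return jsExtrap(44, n, 6);
}

static inline int internalE(int n) {
  static const int I[] = { 15, 16, 17, 20, 21 }; // sizes 2..6
  if (n < 2 || n > MAX_INTERIOR) return INF;
  if (n <= 6) return I[n - 2];
  return jsExtrap(21, n, 6);
}

// energy of the two-pair loop closed by (i,j) with interior pair (k,l)
static inline int twoLoopE(int pij, int pkl, int n1, int n2) {
  if (n1 == 0 && n2 == 0) return STACK[pij][pkl];
  if (n1 + n2 > MAX_INTERIOR) return INF;
  if (n1 == 0 || n2 == 0) return bulgeE(n1 + n2);
  return internalE(n1 + n2);
}

struct FoldDP {
  int n;
  std::vector<int> code;
  std::vector<int> V, WM, W;
  std::string db;

  int& v(int i, int j) { return V[i * n + j]; }
  int& wm(int i, int j) { return WM[i * n + j]; }

  explicit FoldDP(const std::string& seq) : n((int) seq.size()) {
    code.resize(n);
    for (int i = 0; i < n; ++i) code[i] = baseCode(seq[i]);
    V.assign((size_t) n * n, INF);
    WM.assign((size_t) n * n, INF);
    W.assign(n + 1, 0);
    db.assign(n, '.');
  }

  void fill() {
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int pij = pairCode(code[i], code[j]);
        if (pij >= 0) {
          int best = hairpinE(j - i - 1);
          // interior pair (k,l); loop sides capped at MAX_INTERIOR
          int kmax = std::min(i + 1 + MAX_INTERIOR, j - 4);
          for (int k = i + 1; k <= kmax; ++k) {
            int n1 = k - i - 1;
            int lmin = std::max(k + 4, j - 1 - (MAX_INTERIOR - n1));
            for (int l = j - 1; l >= lmin; --l) {
              int pkl = pairCode(code[k], code[l]);
              if (pkl < 0) continue;
              int vin = v(k, l);
              if (vin >= INF) continue;
              int le = twoLoopE(pij, pkl, n1, j - l - 1);
              if (le >= INF) continue;
              if (vin + le < best) best = vin + le;
            }
          }
          // multiloop: >= 2 branches inside
          for (int k = i + 2; k <= j - 2; ++k) {
            int a = wm(i + 1, k), b = wm(k + 1, j - 1);
            if (a >= INF || b >= INF) continue;
            int e = a + b + ML_CLOSE + ML_BRANCH;
            if (e < best) best = e;
          }
          v(i, j) = best;
        }
        // WM over [i, j]
        int best = INF;
        if (v(i, j) < INF) best = v(i, j) + ML_BRANCH;
        if (wm(i + 1, j) < best) best = wm(i + 1, j);
        if (wm(i, j - 1) < best) best = wm(i, j - 1);
        for (int k = i + 1; k < j; ++k) {
          int a = wm(i, k), b = wm(k + 1, j);
          if (a >= INF || b >= INF) continue;
          if (a + b < best) best = a + b;
        }
        wm(i, j) = best;
      }
    }
    // shorter spans for WM: single helix impossible below span 4, leave INF
    for (int j = 1; j <= n; ++j) {
      int best = W[j - 1];
      for (int i = 0; i < j; ++i) {
        int vij = (j - 1 > i) ? v(i, j - 1) : INF;
        if (vij >= INF) continue;
        int prev = (i > 0) ? W[i] : 0;
        if (prev + vij < best) best = prev + vij;
      }
      W[j] = best;
    }
  }

  void traceV(int i, int j);

  void traceWM(int i, int j) {
    if (j < i) return;
    int e = wm(i, j);
    if (e >= INF) return;
    if (j - 1 >= i && wm(i, j - 1) == e) { traceWM(i, j - 1); return; }
    if (i + 1 <= j && wm(i + 1, j) == e) { traceWM(i + 1, j); return; }
    if (v(i, j) < INF && v(i, j) + ML_BRANCH == e) { traceV(i, j); return; }
    for (int k = i + 1; k < j; ++k) {
      if (wm(i, k) < INF && wm(k + 1, j) < INF && wm(i, k) + wm(k + 1, j) == e) {
        traceWM(i, k); traceWM(k + 1, j); return;
      }
    }
  }

  void traceW(int j) {
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 0; i < j; ++i) {
        int vij = (j - 1 > i) ? v(i, j - 1) : INF;
        if (vij >= INF) continue;
        int prev = (i > 0) ? W[i] : 0;
        if (prev + vij == W[j]) { traceV(i, j - 1); j = i; found = true; break; }
      }
      if (!found) break; // defensive; cannot happen on a filled table
    }
  }
};

void FoldDP::traceV(int i, int j) {
  db[i] = '('; db[j] = ')';
  int e = v(i, j);
  int pij = pairCode(code[i], code[j]);
  if (hairpinE(j - i - 1) == e) return;
  int kmax = std::min(i + 1 + MAX_INTERIOR, j - 4);
  for (int k = i + 1; k <= kmax; ++k) {
    int n1 = k - i - 1;
    int lmin = std::max(k + 4, j - 1 - (MAX_INTERIOR - n1));
    for (int l = j - 1; l >= lmin; --l) {
      int pkl = pairCode(code[k], code[l]);
      if (pkl < 0 || v(k, l) >= INF) continue;
      int le = twoLoopE(pij, pkl, n1, j - l - 1);
      if (le < INF && v(k, l) + le == e) { traceV(k, l); return; }
    }
  }
  for (int k = i + 2; k <= j - 2; ++k) {
    int a = wm(i + 1, k), b = wm(k + 1, j - 1);
    if (a >= INF || b >= INF) continue;
    if (a + b + ML_CLOSE + ML_BRANCH == e) {
      traceWM(i + 1, k); traceWM(k + 1, j - 1); return;
    }
  }
}

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq) {
  int n = (int) seq.size();
  if (n == 0) return List::create(_["dg10"] = 0, _["db"] = "");
  FoldDP dp(seq);
  dp.fill();
  int e = dp.W[n];
  if (e < 0) dp.traceW(n); else e = 0;
  return List::create(_["dg10"] = e, _["db"] = dp.db);
}

// Loop-decomposition scoring of an explicit structure; the reference scorer
// shared by the enumeration oracle. Returns INF-coded NA for invalid input.
static int scoreStructure(const std::vector<int>& code,
                          const std::vector<int>& partner) {
  int n = (int) code.size();
  int total = 0;
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j <= i) continue;
    int pij = pairCode(code[i], code[j]);
    if (pij < 0) return INF;
    // children: pairs directly enclosed by (i,j)
    int unpaired = 0, nchild = 0;
    int firstK = -1, firstL = -1;
    for (int k = i + 1; k < j; ++k) {
      if (partner[k] < 0) { ++unpaired; continue; }
      if (partner[k] < k) return INF; // crossing/malformed
      ++nchild;
      if (nchild == 1) { firstK = k; firstL = partner[k]; }
      k = partner[k];
    }
    int e;
    if (nchild == 0) {
      e = hairpinE(j - i - 1);
    } else if (nchild == 1) {
      int pkl = pairCode(code[firstK], code[firstL]);
      if (pkl < 0) return INF;
      e = twoLoopE(pij, pkl, firstK - i - 1, j - firstL - 1);
    } else {
      e = ML_CLOSE + ML_BRANCH * (nchild + 1);
    }
    if (e >= INF) return INF;
    total += e;
  }
  return total;
}

static bool parseDotBracket(const std::string& db, std::vector<int>& partner) {
  int n = (int) db.size();
  partner.assign(n, -1);
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (db[i] == '(') stack.push_back(i);
    else if (db[i] == ')') {
      if (stack.empty()) return false;
      int j = stack.back(); stack.pop_back();
      partner[j] = i; partner[i] = j;
    } else if (db[i] != '.') return false;
  }
  return stack.empty();
}

// [[Rcpp::export]]
double score_structure_cpp(std::string seq, std::string db) {
  if (seq.size() != db.size()) stop("sequence and structure lengths differ");
  std::vector<int> code(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) code[i] = baseCode(seq[i]);
  std::vector<int> partner;
  if (!parseDotBracket(db, partner)) stop("unbalanced dot-bracket string");
  int e = scoreStructure(code, partner);
  if (e >= INF) return NA_REAL;
  return e / 10.0;
}

// Exhaustive enumeration of every nested structure (backtracking over
// '.', '(' and ')') scored with the loop-decomposition scorer above.
// Independent of the dynamic program; intended for short sequences only.
struct Enumerator {
  const std::vector<int>& code;
  int n;
  std::vector<int> partner;
  std::vector<int> open;
  int best;

  explicit Enumerator(const std::vector<int>& c)
    : code(c), n((int) c.size()), partner(c.size(), -1), best(0) {}

  void run(int pos) {
    if (pos == n) {
      if (open.empty()) {
        int e = scoreStructure(code, partner);
        if (e < best) best = e;
      }
      return;
    }
    if ((int) open.size() > n - pos) return; // cannot close remaining
    // unpaired
    run(pos + 1);
    // close the innermost open bracket
    if (!open.empty()) {
      int i = open.back();
      if (pos - i >= 4 && pairCode(code[i], code[pos]) >= 0) {
        open.pop_back();
        partner[i] = pos; partner[pos] = i;
        run(pos + 1);
        partner[i] = -1; partner[pos] = -1;
        open.push_back(i);
      }
    }
    // open a bracket
    if (code[pos] != 4 && n - pos >= 5) {
      open.push_back(pos);
      run(pos + 1);
      open.pop_back();
    }
  }
};

// [[Rcpp::export]]
double enumerate_mfe_cpp(std::string seq) {
  int n = (int) seq.size();
  if (n > 40) stop("enumeration oracle is limited to sequences <= 40 nt");
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = baseCode(seq[i]);
  Enumerator en(code);
  en.run(0);
  return en.best / 10.0;
}

// ---------------------------------------------------------------------------
// Gapless homology scanner: every full-query-length window on either strand
// of the subject with Hamming distance <= max_mm. 'N' matches nothing.

static inline char complementChar(char c) {
  switch (c) {
    case 'A': return 'U'; case 'U': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
List gapless_scan_cpp(std::string query, std::string subject, int max_mm) {
  int m = (int) query.size(), n = (int) subject.size();
  std::string rcq(m, 'N');
  for (int i = 0; i < m; ++i) rcq[m - 1 - i] = complementChar(query[i]);

  std::vector<int> starts, mms;
  std::vector<std::string> strands, positions, subseqs;

  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = (strand == 0) ? query : rcq;
    for (int s = 0; s + m <= n; ++s) {
      int mm = 0;
      for (int k = 0; k < m; ++k) {
        char a = q[k], b = subject[s + k];
        if (a != b || a == 'N') { if (++mm > max_mm) break; }
      }
      if (mm > max_mm) continue;
      // mismatch positions, 1-based along the query (not its complement)
      std::string pos;
      for (int k = 0; k < m; ++k) {
        char a = q[k], b = subject[s + k];
        if (a != b || a == 'N') {
          int qpos = (strand == 0) ? (k + 1) : (m - k);
          if (!pos.empty()) pos += ",";
          pos += std::to_string(qpos);
        }
      }
      starts.push_back(s);
      mms.push_back(mm);
      strands.push_back(strand == 0 ? "+" : "-");
      positions.push_back(pos);
      subseqs.push_back(subject.substr(s, m));
    }
  }
  return List::create(_["est_start"] = starts, _["strand"] = strands,
                      _["mismatches"] = mms, _["mismatch_positions"] = positions,
                      _["aligned_est_subseq"] = subseqs);
}
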