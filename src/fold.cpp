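// Minimum-free-energy RNA secondary structure engine.
//
// A Zuker-style dynamic program over a simplified nearest-neighbor model:
// Turner-style stacking energies for the 16 canonical/wobble pair stacks,
// length-dependent hairpin/bulge/internal loop penalties, and an affine
// multiloop penalty. Interior loops are capped at MAXLOOP unpaired bases
// (standard practice; keeps the DP at O(n^2 * MAXLOOP^2 + n^3)).
//
// c_enumerate_structures() is an independent brute-force route over ALL
// well-nested structures (compatible pairs, min hairpin loop 3) scoring each
// by explicit loop decomposition; it shares only the parameter tables and
// serves as the oracle for the DP at small n.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double E_INF = 1e9;
static const int MIN_HP = 3;     // minimum hairpin loop size
static const int MAXLOOP = 15;   // interior/bulge unpaired-base cap
static const double ML_A = 3.4;  // multiloop closing penalty
static const double ML_B = 0.4;  // per-branch penalty
static const double ML_C = 0.0;  // per-unpaired-base penalty
static const double LXC = 1.078; // 1.75 * RT at 37C, loop length extrapolation

// base codes A=0 C=1 G=2 U/T=3, -1 invalid
static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
  }
  return -1;
}

// pair types in Vienna order: 0 CG, 1 GC, 2 GU, 3 UG, 4 AU, 5 UA, -1 none
static inline int pairType(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

// stacking free energies (kcal/mol); rows = outer pair (i,j), cols = inner
// pair (i+1,j-1), both in Vienna order. Turner-style values.
static const double STACK[6][6] = {
  /* CG */ {-3.30, -3.40, -2.10, -1.40, -2.10, -2.10},
  /* GC */ {-3.40, -3.30, -2.50, -1.50, -2.20, -2.40},
  /* GU */ {-2.10, -2.50, -1.40,  0.30, -1.30, -1.00},
  /* UG */ {-1.40, -1.50,  0.30, -0.50, -0.60, -1.00},
  /* AU */ {-2.10, -2.20, -1.30, -0.60, -0.90, -1.10},
  /* UA */ {-2.10, -2.40, -1.00, -1.00, -1.30, -0.90}
};

static double hairpinE(int n) {
  static const double H[] = {5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
  if (n < MIN_HP) return E_INF;
  if (n <= 9) return H[n - 3];
  return 6.4 + LXC * std::log((double)n / 9.0);
}

static double bulgeE(int n) {
  static const double B[] = {3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
  if (n <= 6) return B[n - 1];
  return 4.4 + LXC * std::log((double)n / 6.0);
}

static double internalE(int n1, int n2) {
  int n = n1 + n2;
  static const double I[] = {0.9, 1.3, 1.7, 1.8, 2.0};
  double base = (n <= 6) ? I[n - 2] : 2.0 + LXC * std::log((double)n / 6.0);
  double asym = 0.5 * std::abs(n1 - n2);
  if (asym > 3.0) asym = 3.0;
  return base + asym;
}

// energy of the loop closed by pair (i,j) with single inner pair (p,q)
static double twoLoopE(const std::vector<int>& b, int i, int j, int p, int q) {
  int n1 = p - i - 1, n2 = j - q - 1;
  if (n1 == 0 && n2 == 0)
    return STACK[pairType(b[i], b[j])][pairType(b[p], b[q])];
  if (n1 == 0 || n2 == 0) return bulgeE(n1 + n2);
  return internalE(n1, n2);
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> b(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    b[k] = baseCode(s[k]);
    if (b[k] < 0) stop("invalid base '%s' at position %d (alphabet is A,C,G,U/T)",
                       std::string(1, s[k]).c_str(), (int)k + 1);
  }
  return b;
}

// ---------------------------------------------------------------------------
// Loop-decomposition energy of a given structure (pair table, -1 = unpaired).
// Used by the brute-force enumerator and exported for structure evaluation.
// ---------------------------------------------------------------------------
static double evalPairTable(const std::vector<int>& b, const std::vector<int>& pt) {
  int n = (int)b.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = pt[i];
    if (j <= i) continue; // closing pairs only
    // scan the interior of (i,j) at top nesting level
    std::vector<std::pair<int, int> > branches;
    int unpaired = 0;
    int k = i + 1;
    while (k < j) {
      if (pt[k] > k) { branches.push_back(std::make_pair(k, pt[k])); k = pt[k] + 1; }
      else { ++unpaired; ++k; }
    }
    if (branches.empty()) {
      e += hairpinE(j - i - 1);
    } else if (branches.size() == 1) {
      e += twoLoopE(b, i, j, branches[0].first, branches[0].second);
    } else {
      e += ML_A + ML_B * (double)(branches.size() + 1) + ML_C * (double)unpaired;
    }
  }
  return e;
}

static std::vector<int> parseDotBracket(const std::string& db) {
  std::vector<int> pt(db.size(), -1);
  std::vector<int> st;
  for (size_t k = 0; k < db.size(); ++k) {
    if (db[k] == '(') st.push_back((int)k);
    else if (db[k] == ')') {
      if (st.empty()) stop("unbalanced dot-bracket string");
      pt[k] = st.back(); pt[st.back()] = (int)k; st.pop_back();
    } else if (db[k] != '.') stop("dot-bracket may contain only '.', '(', ')'");
  }
  if (!st.empty()) stop("unbalanced dot-bracket string");
  return pt;
}

// [[Rcpp::export]]
double c_eval_structure(std::string seq, std::string db) {
  if (seq.size() != db.size()) stop("sequence and structure lengths differ");
  std::vector<int> b = encode(seq);
  std::vector<int> pt = parseDotBracket(db);
  for (size_t k = 0; k < pt.size(); ++k)
    if (pt[k] >= 0 && (int)k < pt[k] && pairType(b[k], b[pt[k]]) < 0)
      stop("non-canonical pair at %d-%d", (int)k + 1, pt[k] + 1);
  return evalPairTable(b, pt);
}

// ---------------------------------------------------------------------------
// MFE dynamic program with traceback
// ---------------------------------------------------------------------------

struct FoldDP {
  const std::vector<int>& b;
  int n;
  std::vector<double> V, M;
  std::vector<double> W;
  FoldDP(const std::vector<int>& bb) : b(bb), n((int)bb.size()),
    V(n * n, E_INF), M(n * n, E_INF), W(n + 1, 0.0) {}
  inline double& v(int i, int j) { return V[i * n + j]; }
  inline double& m(int i, int j) { return M[i * n + j]; }

  void run() {
    for (int j = 0; j < n; ++j) {
      for (int i = j - 1; i >= 0; --i) {
        // --- V(i,j): i paired with j
        double best = E_INF;
        if (pairType(b[i], b[j]) >= 0 && j - i - 1 >= MIN_HP) {
          best = hairpinE(j - i - 1);
          // interior / stack / bulge
          int pmax = std::min(i + MAXLOOP + 1, j - 1 - MIN_HP - 1);
          for (int p = i + 1; p <= pmax; ++p) {
            int qmin = std::max(p + MIN_HP + 1, j - 1 - (MAXLOOP - (p - i - 1)));
            for (int q = j - 1; q >= qmin; --q) {
              if (v(p, q) >= E_INF) continue;
              double e = v(p, q) + twoLoopE(b, i, j, p, q);
              if (e < best) best = e;
            }
          }
          // multiloop: a + b(closing) + M(i+1,k) + M(k+1,j-1)
          for (int k = i + 2; k < j - 2; ++k) {
            double e1 = m(i + 1, k), e2 = m(k + 1, j - 1);
            if (e1 >= E_INF || e2 >= E_INF) continue;
            double e = ML_A + ML_B + e1 + e2;
            if (e < best) best = e;
          }
        }
        v(i, j) = best;
        // --- M(i,j): >=1 branch inside a multiloop
        double bm = E_INF;
        if (v(i, j) < E_INF) bm = v(i, j) + ML_B;
        if (i + 1 <= j && m(i + 1, j) + ML_C < bm) bm = m(i + 1, j) + ML_C;
        if (i <= j - 1 && m(i, j - 1) + ML_C < bm) bm = m(i, j - 1) + ML_C;
        for (int k = i; k < j; ++k) {
          double e1 = m(i, k), e2 = m(k + 1, j);
          if (e1 >= E_INF || e2 >= E_INF) continue;
          if (e1 + e2 < bm) bm = e1 + e2;
        }
        m(i, j) = bm;
      }
    }
    // exterior
    W[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double best = W[j - 1];
      for (int i = 0; i < j; ++i) {
        if (v(i, j - 1) >= E_INF) continue;
        double e = W[i] + v(i, j - 1);
        if (e < best) best = e;
      }
      W[j] = best;
    }
  }

  // traceback; deterministic preference order
  void traceback(std::vector<int>& pt) {
    const double EPS = 1e-7;
    pt.assign(n, -1);
    std::vector<std::pair<std::pair<int, int>, int> > stack; // ((i,j), state) 0=V 1=M
    // exterior
    {
      int j = n;
      while (j > 0) {
        if (std::abs(W[j] - W[j - 1]) < EPS) { --j; continue; }
        bool moved = false;
        for (int i = 0; i < j && !moved; ++i) {
          if (v(i, j - 1) < E_INF && std::abs(W[j] - (W[i] + v(i, j - 1))) < EPS) {
            pt[i] = j - 1; pt[j - 1] = i;
            stack.push_back(std::make_pair(std::make_pair(i, j - 1), 0));
            j = i; moved = true;
          }
        }
        if (!moved) --j; // numerical safety
      }
    }
    while (!stack.empty()) {
      int i = stack.back().first.first, j = stack.back().first.second;
      int state = stack.back().second;
      stack.pop_back();
      if (state == 0) { // V(i,j), i-j already paired
        double target = v(i, j);
        // interior first (prefers stacking => more pairs), then multi, then hairpin
        bool done = false;
        int pmax = std::min(i + MAXLOOP + 1, j - 1 - MIN_HP - 1);
        for (int p = i + 1; p <= pmax && !done; ++p) {
          int qmin = std::max(p + MIN_HP + 1, j - 1 - (MAXLOOP - (p - i - 1)));
          for (int q = j - 1; q >= qmin && !done; --q) {
            if (v(p, q) >= E_INF) continue;
            if (std::abs(target - (v(p, q) + twoLoopE(b, i, j, p, q))) < EPS) {
              pt[p] = q; pt[q] = p;
              stack.push_back(std::make_pair(std::make_pair(p, q), 0));
              done = true;
            }
          }
        }
        for (int k = i + 2; k < j - 2 && !done; ++k) {
          double e1 = m(i + 1, k), e2 = m(k + 1, j - 1);
          if (e1 >= E_INF || e2 >= E_INF) continue;
          if (std::abs(target - (ML_A + ML_B + e1 + e2)) < EPS) {
            stack.push_back(std::make_pair(std::make_pair(i + 1, k), 1));
            stack.push_back(std::make_pair(std::make_pair(k + 1, j - 1), 1));
            done = true;
          }
        }
        // else hairpin: nothing to do
      } else { // M(i,j)
        double target = m(i, j);
        if (v(i, j) < E_INF && std::abs(target - (v(i, j) + ML_B)) < EPS) {
          pt[i] = j; pt[j] = i;
          stack.push_back(std::make_pair(std::make_pair(i, j), 0));
          continue;
        }
        if (i + 1 <= j && m(i + 1, j) < E_INF && std::abs(target - (m(i + 1, j) + ML_C)) < EPS) {
          stack.push_back(std::make_pair(std::make_pair(i + 1, j), 1));
          continue;
        }
        if (i <= j - 1 && m(i, j - 1) < E_INF && std::abs(target - (m(i, j - 1) + ML_C)) < EPS) {
          stack.push_back(std::make_pair(std::make_pair(i, j - 1), 1));
          continue;
        }
        bool done = false;
        for (int k = i; k < j && !done; ++k) {
          double e1 = m(i, k), e2 = m(k + 1, j);
          if (e1 >= E_INF || e2 >= E_INF) continue;
          if (std::abs(target - (e1 + e2)) < EPS) {
            stack.push_back(std::make_pair(std::make_pair(i, k), 1));
            stack.push_back(std::make_pair(std::make_pair(k + 1, j), 1));
            done = true;
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
List c_fold(std::string seq) {
  std::vector<int> b = encode(seq);
  int n = (int)b.size();
  if (n < 1) stop("empty sequence");
  FoldDP dp(b);
  dp.run();
  double mfe = dp.W[n];
  std::string db(n, '.');
  if (mfe < -1e-9) {
    std::vector<int> pt;
    dp.traceback(pt);
    for (int k = 0; k < n; ++k)
      if (pt[k] > k) { db[k] = '('; db[pt[k]] = ')'; }
    // recompute the energy of the traced structure (numerical audit)
    mfe = evalPairTable(b, pt);
  } else {
    mfe = 0.0;
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// ---------------------------------------------------------------------------
// Brute-force enumeration oracle
// ---------------------------------------------------------------------------

struct Enumerator {
  const std::vector<int>& b;
  int n;
  std::vector<int> pt;
  double bestE;
  std::vector<int> bestPt;
  long long count;
  long long cap;
  Enumerator(const std::vector<int>& bb, long long cp)
    : b(bb), n((int)bb.size()), pt(bb.size(), -1), bestE(1.0), count(0), cap(cp) {
    bestPt = pt;
  }
  void emit() {
    ++count;
    if (count > cap) stop("structure enumeration exceeded cap of %lld", cap);
    double e = evalPairTable(b, pt);
    if (e < bestE) { bestE = e; bestPt = pt; }
  }
  // enumerate region [i,j), then the segments queued in rest
  void go(int i, int j, std::vector<std::pair<int, int> >& rest) {
    if (i >= j) {
      if (rest.empty()) { emit(); return; }
      std::pair<int, int> s = rest.back();
      rest.pop_back();
      go(s.first, s.second, rest);
      rest.push_back(s);
      return;
    }
    go(i + 1, j, rest); // i unpaired
    for (int k = i + MIN_HP + 1; k < j; ++k) {
      if (pairType(b[i], b[k]) < 0) continue;
      pt[i] = k; pt[k] = i;
      rest.push_back(std::make_pair(k + 1, j));
      go(i + 1, k, rest);
      rest.pop_back();
      pt[i] = -1; pt[k] = -1;
    }
  }
};

// [[Rcpp::export]]
List c_enumerate_structures(std::string seq, double cap = 5e7) {
  std::vector<int> b = encode(seq);
  int n = (int)b.size();
  if (n > 40) stop("enumeration oracle restricted to sequences <= 40 nt");
  Enumerator en(b, (long long)cap);
  std::vector<std::pair<int, int> > rest;
  en.go(0, n, rest);
  std::string db(n, '.');
  double best = en.bestE;
  if (best >= 0.0) { best = 0.0; } // open chain (energy 0) beats any positive structure
  else {
    for (int k = 0; k < n; ++k)
      if (en.bestPt[k] > k) { db[k] = '('; db[en.bestPt[k]] = ')'; }
  }
  return List::create(_["structure"] = db, _["mfe"] = best,
                      _["n_structures"] = (double)en.count);
}
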