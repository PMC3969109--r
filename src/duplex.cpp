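// Intermolecular RNA-RNA duplex folding (minimum free energy) under a
// nearest-neighbor stacking model with an affine interior/bulge-loop
// penalty and a duplex initiation penalty. Only intermolecular pairs are
// formed; pairs nest (i increasing in strand 1, j decreasing in strand 2).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static inline int rna_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;  // N: unpairable
  }
}

// pair types indexed as in R: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5; -1 unpairable
static inline int pair_type(int a, int b) {
  if (a < 0 || b < 0) return -1;
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// [[Rcpp::export]]
List cpp_duplex_fold(std::string s1, std::string s2, NumericMatrix stacks,
                     double init_penalty, double loop_a, double loop_b,
                     int max_loop) {
  const int n1 = (int)s1.size(), n2 = (int)s2.size();
  std::vector<int> c1(n1), c2(n2);
  for (int i = 0; i < n1; ++i) c1[i] = rna_code(s1[i]);
  for (int j = 0; j < n2; ++j) c2[j] = rna_code(s2[j]);

  const double INF = std::numeric_limits<double>::infinity();
  // B[i][j]: energy of the best chain whose last pair (largest i, smallest j)
  // is (i, j); includes the initiation penalty.
  std::vector<std::vector<double> > B(n1, std::vector<double>(n2, INF));
  std::vector<std::vector<int> > Pi(n1, std::vector<int>(n2, -1)),
      Pj(n1, std::vector<int>(n2, -1));

  double best = INF; int bi = -1, bj = -1;
  for (int i = 0; i < n1; ++i) {
    for (int j = n2 - 1; j >= 0; --j) {
      int p = pair_type(c1[i], c2[j]);
      if (p < 0) continue;
      double e = init_penalty;  // chain starting at this pair
      int pi = -1, pj = -1;
      for (int k = i - 1; k >= 0; --k) {
        int un1 = i - k - 1;
        if (un1 > max_loop) break;
        for (int l = j + 1; l < n2; ++l) {
          int un2 = l - j - 1;
          if (un1 + un2 > max_loop) break;
          if (B[k][l] == INF) continue;
          int q = pair_type(c1[k], c2[l]);
          double step;
          if (un1 == 0 && un2 == 0) step = stacks(q, p);
          else step = loop_a + loop_b * (un1 + un2);
          double cand = B[k][l] + step;
          if (cand < e) { e = cand; pi = k; pj = l; }
        }
      }
      B[i][j] = e; Pi[i][j] = pi; Pj[i][j] = pj;
      if (e < best) { best = e; bi = i; bj = j; }
    }
  }

  std::string db(n1 + 1 + n2, '.');
  db[n1] = '&';
  double dG = 0.0;
  int npairs = 0;
  if (bi >= 0 && best < 0) {
    dG = best;
    int i = bi, j = bj;
    while (i >= 0) {
      db[i] = '(';
      db[n1 + 1 + j] = ')';
      ++npairs;
      int ni = Pi[i][j], nj = Pj[i][j];
      i = ni; j = nj;
    }
  }
  return List::create(_["dG"] = dG, _["structure"] = db, _["n_pairs"] = npairs);
}
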