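// Boltzmann ensemble engine for a compact nearest-neighbor RNA model:
// McCaskill-style partition function over all secondary structures with a
// minimum hairpin loop, loop-decomposed energies (stacking, affine hairpin /
// interior / multiloop penalties), and stochastic traceback sampling.
// Bases are encoded 0=A, 1=C, 2=G, 3=U.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

struct Model {
  double stack[6][6];
  double hairpin_a, hairpin_b;
  double interior_a, interior_b;
  double ml_a, ml_b, ml_c;
  int min_hairpin, max_interior;
  double RT;
};

// pair indices follow the order AU, UA, CG, GC, GU, UG
inline int pair_index(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Fold {
  int n;
  const std::vector<int>& s;
  const Model& m;
  std::vector<double> Zb, Zm, Zm1;   // n*n, index i*n+j
  std::vector<double> Ze;            // n+1 prefix exterior
  Fold(const std::vector<int>& seq, const Model& mod)
      : n((int)seq.size()), s(seq), m(mod),
        Zb(n * n, 0.0), Zm(n * n, 0.0), Zm1(n * n, 0.0), Ze(n + 1, 0.0) {}

  inline double w(double e) const { return std::exp(-e / m.RT); }
  inline double eh(int size) const {
    return m.hairpin_a + m.hairpin_b * (size - m.min_hairpin);
  }
  inline double eint(int size) const {
    return m.interior_a + m.interior_b * size;
  }
  inline bool pairable(int i, int j) const {
    return j - i - 1 >= m.min_hairpin && pair_index(s[i], s[j]) >= 0;
  }

  void fill() {
    for (int span = m.min_hairpin + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // Zb ------------------------------------------------------------
        if (pairable(i, j)) {
          double z = w(eh(j - i - 1));
          int pij = pair_index(s[i], s[j]);
          for (int k = i + 1; k < j - m.min_hairpin; ++k) {
            if (k - i - 1 > m.max_interior) break;
            for (int l = j - 1; l > k + m.min_hairpin; --l) {
              int size = (k - i - 1) + (j - l - 1);
              if (size > m.max_interior) break;  // l decreasing grows size
              if (!pairable(k, l)) continue;
              double zkl = Zb[k * n + l];
              if (zkl == 0.0) continue;
              if (size == 0)
                z += w(m.stack[pij][pair_index(s[k], s[l])]) * zkl;
              else
                z += w(eint(size)) * zkl;
            }
          }
          // multiloop: closing pair (i,j), >= 2 inner branches
          double ml = 0.0;
          for (int h = i + 2; h <= j - 2; ++h) {
            double left = Zm[(i + 1) * n + (h - 1)];
            if (left == 0.0) continue;
            double right = Zm1[h * n + (j - 1)];
            if (right == 0.0) continue;
            ml += left * right;
          }
          z += w(m.ml_a + m.ml_b) * ml;
          Zb[i * n + j] = z;
        }
        // Zm1: exactly one branch starting at i, trailing unpaired --------
        {
          double z = 0.0;
          for (int l = i + m.min_hairpin + 1; l <= j; ++l) {
            if (!pairable(i, l)) continue;
            double zb = Zb[i * n + l];
            if (zb == 0.0) continue;
            z += zb * w(m.ml_b + m.ml_c * (j - l));
          }
          Zm1[i * n + j] = z;
        }
        // Zm: >= 1 branch, decomposition by start of last branch ----------
        {
          double z = 0.0;
          for (int k = i; k <= j - m.min_hairpin - 1; ++k) {
            double z1 = Zm1[k * n + j];
            if (z1 == 0.0) continue;
            double left = w(m.ml_c * (k - i));
            if (k > i) left += Zm[i * n + (k - 1)];
            z += left * z1;
          }
          Zm[i * n + j] = z;
        }
      }
    }
    Ze[0] = 1.0;
    for (int j = 1; j <= n; ++j) {
      double z = Ze[j - 1];
      for (int i = 0; i < j; ++i) {
        if (!pairable(i, j - 1)) continue;
        double zb = Zb[i * n + (j - 1)];
        if (zb > 0.0) z += Ze[i] * zb;
      }
      Ze[j] = z;
    }
  }

  // ---- stochastic traceback -------------------------------------------
  void sample_zb(int i, int j, std::string& db) {
    db[i] = '('; db[j] = ')';
    double r = unif_rand() * Zb[i * n + j];
    double acc = w(eh(j - i - 1));
    if (r < acc) return;  // hairpin
    int pij = pair_index(s[i], s[j]);
    for (int k = i + 1; k < j - m.min_hairpin; ++k) {
      if (k - i - 1 > m.max_interior) break;
      for (int l = j - 1; l > k + m.min_hairpin; --l) {
        int size = (k - i - 1) + (j - l - 1);
        if (size > m.max_interior) break;
        if (!pairable(k, l)) continue;
        double zkl = Zb[k * n + l];
        if (zkl == 0.0) continue;
        double term = (size == 0)
          ? w(m.stack[pij][pair_index(s[k], s[l])]) * zkl
          : w(eint(size)) * zkl;
        acc += term;
        if (r < acc) { sample_zb(k, l, db); return; }
      }
    }
    double mlw = w(m.ml_a + m.ml_b);
    for (int h = i + 2; h <= j - 2; ++h) {
      double left = Zm[(i + 1) * n + (h - 1)];
      if (left == 0.0) continue;
      double right = Zm1[h * n + (j - 1)];
      if (right == 0.0) continue;
      acc += mlw * left * right;
      if (r < acc) {
        sample_zm(i + 1, h - 1, db);
        sample_zm1(h, j - 1, db);
        return;
      }
    }
    // numerical slack: fall back to the hairpin case
  }

  void sample_zm1(int i, int j, std::string& db) {
    double r = unif_rand() * Zm1[i * n + j];
    double acc = 0.0;
    int last = -1;
    for (int l = i + m.min_hairpin + 1; l <= j; ++l) {
      if (!pairable(i, l)) continue;
      double zb = Zb[i * n + l];
      if (zb == 0.0) continue;
      last = l;
      acc += zb * w(m.ml_b + m.ml_c * (j - l));
      if (r < acc) { sample_zb(i, l, db); return; }
    }
    if (last >= 0) sample_zb(i, last, db);
  }

  void sample_zm(int i, int j, std::string& db) {
    double r = unif_rand() * Zm[i * n + j];
    double acc = 0.0;
    for (int k = i; k <= j - m.min_hairpin - 1; ++k) {
      double z1 = Zm1[k * n + j];
      if (z1 == 0.0) continue;
      double unp = w(m.ml_c * (k - i)) * z1;
      acc += unp;
      if (r < acc) { sample_zm1(k, j, db); return; }
      if (k > i) {
        double rec = Zm[i * n + (k - 1)] * z1;
        acc += rec;
        if (r < acc) { sample_zm(i, k - 1, db); sample_zm1(k, j, db); return; }
      }
    }
    // slack fallback: single branch at the first feasible k
    for (int k = i; k <= j - m.min_hairpin - 1; ++k)
      if (Zm1[k * n + j] > 0.0) { sample_zm1(k, j, db); return; }
  }

  std::string sample_exterior() {
    std::string db(n, '.');
    int j = n;
    while (j > 0) {
      double r = unif_rand() * Ze[j];
      if (r < Ze[j - 1]) { --j; continue; }
      double acc = Ze[j - 1];
      bool done = false;
      for (int i = 0; i < j; ++i) {
        if (!pairable(i, j - 1)) continue;
        double zb = Zb[i * n + (j - 1)];
        if (zb == 0.0) continue;
        acc += Ze[i] * zb;
        if (r < acc) { sample_zb(i, j - 1, db); j = i; done = true; break; }
      }
      if (!done) --j;  // numerical slack
    }
    return db;
  }
};

Model model_from_list(List ml) {
  Model m;
  NumericMatrix st = ml["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) m.stack[a][b] = st(a, b);
  m.hairpin_a = as<double>(ml["hairpin_a"]);
  m.hairpin_b = as<double>(ml["hairpin_b"]);
  m.interior_a = as<double>(ml["interior_a"]);
  m.interior_b = as<double>(ml["interior_b"]);
  m.ml_a = as<double>(ml["ml_a"]);
  m.ml_b = as<double>(ml["ml_b"]);
  m.ml_c = as<double>(ml["ml_c"]);
  m.min_hairpin = as<int>(ml["min_hairpin"]);
  m.max_interior = as<int>(ml["max_interior"]);
  m.RT = as<double>(ml["RT"]);
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_fold_sample")]]
List cpp_fold_sample(IntegerVector seq, List model, int k) {
  std::vector<int> s(seq.begin(), seq.end());
  Model m = model_from_list(model);
  Fold f(s, m);
  f.fill();
  CharacterVector out(k);
  GetRNGstate();
  for (int r = 0; r < k; ++r) out[r] = f.sample_exterior();
  PutRNGstate();
  return List::create(_["structures"] = out,
                      _["logZ"] = std::log(f.Ze[s.size()]));
}

// [[Rcpp::export(name = ".cpp_partition")]]
double cpp_partition(IntegerVector seq, List model) {
  std::vector<int> s(seq.begin(), seq.end());
  Model m = model_from_list(model);
  Fold f(s, m);
  f.fill();
  return f.Ze[s.size()];
}
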