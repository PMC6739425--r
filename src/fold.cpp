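// Probing-directed RNA folding: MFE dynamic program and McCaskill-style
// partition function over a simplified nearest-neighbor model
// (stacking-energy table + affine hairpin/bulge/internal/multiloop
// penalties, per-paired-nucleotide reactivity pseudo-energies).
//
// Unambiguous decomposition shared by MFE (min-plus) and PF (sum-product):
//   B(i,j)  : [i,j] closed by pair (i,j); hairpin | interior | multiloop
//   M1(i,j) : exactly one multiloop branch starting at i, rest 3' unpaired
//   M(i,j)  : >= 1 multiloop branches, decomposed on the start of the last
//   W       : exterior (unpaired bases free)
// PF values are scaled by u^span with u = exp(E0/RT), E0 = min(0, MFE)/n,
// so the dominant structure has weight ~1 and no overflow occurs.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;

struct Model {
  double stack[7][7];           // [outer][inner], pair types 1..6
  double ha, hb;                // hairpin  a + b*size
  double ba, bb;                // bulge    a + b*size
  double ia, ib;                // internal a + b*(s1+s2)
  double mla, mlb, mlc;         // multiloop closing / branch / unpaired
  int h;                        // min hairpin loop
  int L;                        // max interior loop (s1+s2)
  double RT;
};

static inline int ptype(int a, int b) {
  // bases: 0=A 1=C 2=G 3=U
  if (a == 0 && b == 3) return 1;  // AU
  if (a == 3 && b == 0) return 2;  // UA
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 1 && b == 2) return 4;  // CG
  if (a == 2 && b == 3) return 5;  // GU
  if (a == 3 && b == 2) return 6;  // UG
  return 0;
}

static Model read_model(List params) {
  Model m;
  NumericMatrix st = params["stack"];
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b) m.stack[a][b] = st(a - 1, b - 1);
  m.ha = params["hairpin_a"]; m.hb = params["hairpin_b"];
  m.ba = params["bulge_a"];   m.bb = params["bulge_b"];
  m.ia = params["internal_a"]; m.ib = params["internal_b"];
  m.mla = params["ml_a"]; m.mlb = params["ml_b"]; m.mlc = params["ml_c"];
  m.h = as<int>(params["min_hairpin"]);
  m.L = as<int>(params["max_interior"]);
  m.RT = params["RT"];
  return m;
}

// interior-loop / stack / bulge energy for outer (i,j) enclosing (k,l)
static inline double il_energy(const Model& m, int pij, int pkl,
                               int s1, int s2) {
  if (s1 == 0 && s2 == 0) return m.stack[pij][pkl];
  if (s1 == 0 || s2 == 0) return m.ba + m.bb * (s1 + s2);
  return m.ia + m.ib * (s1 + s2);
}

struct Arrays {
  int n;
  std::vector<double> B, M, M1;
  std::vector<double> W;
  double at(const std::vector<double>& A, int i, int j) const {
    return A[(size_t)i * (n + 2) + j];
  }
  Arrays(int n_) : n(n_),
    B((size_t)(n_ + 2) * (n_ + 2), INF),
    M((size_t)(n_ + 2) * (n_ + 2), INF),
    M1((size_t)(n_ + 2) * (n_ + 2), INF),
    W(n_ + 1, 0.0) {}
};

#define IDX(i, j) ((size_t)(i) * (n + 2) + (j))

static void mfe_fill(const std::vector<int>& s, const std::vector<double>& pe,
                     const Model& m, Arrays& A) {
  int n = A.n;
  for (int span = m.h + 1; span <= n - 1; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      int pij = ptype(s[i], s[j]);
      // ---- B(i,j)
      if (pij > 0 && j - i - 1 >= m.h) {
        double best = m.ha + m.hb * (j - i - 1);      // hairpin
        for (int k = i + 1; k <= j - 2 && k - i - 1 <= m.L; ++k) {
          int s1 = k - i - 1;
          int lmin = k + m.h + 1;
          int lmax = j - 1;
          for (int l = lmax; l >= lmin; --l) {
            int s2 = j - l - 1;
            if (s1 + s2 > m.L) break;
            double vb = A.B[IDX(k, l)];
            if (vb >= INF / 2) continue;
            int pkl = ptype(s[k], s[l]);
            double e = il_energy(m, pij, pkl, s1, s2) + vb;
            if (e < best) best = e;
          }
        }
        for (int mm = i + 2; mm <= j - 2; ++mm) {      // multiloop
          double a1 = A.M[IDX(i + 1, mm - 1)], a2 = A.M1[IDX(mm, j - 1)];
          if (a1 >= INF / 2 || a2 >= INF / 2) continue;
          double e = m.mla + a1 + a2;
          if (e < best) best = e;
        }
        A.B[IDX(i, j)] = best + pe[i] + pe[j];
      }
      // ---- M1(i,j)
      {
        double best = INF;
        for (int l = i + m.h + 1; l <= j; ++l) {
          double vb = A.B[IDX(i, l)];
          if (vb >= INF / 2) continue;
          double e = vb + m.mlb + m.mlc * (j - l);
          if (e < best) best = e;
        }
        A.M1[IDX(i, j)] = best;
      }
      // ---- M(i,j)
      {
        double best = INF;
        for (int k = i; k <= j; ++k) {
          double m1 = A.M1[IDX(k, j)];
          if (m1 >= INF / 2) continue;
          double e = m.mlc * (k - i) + m1;
          if (e < best) best = e;
          if (k > i) {
            double mm = A.M[IDX(i, k - 1)];
            if (mm < INF / 2) {
              e = mm + m1;
              if (e < best) best = e;
            }
          }
        }
        A.M[IDX(i, j)] = best;
      }
    }
  }
  for (int j = 1; j <= n; ++j) {
    double best = A.W[j - 1];
    for (int i = 1; i <= j; ++i) {
      double vb = A.B[IDX(i, j)];
      if (vb >= INF / 2) continue;
      double e = A.W[i - 1] + vb;
      if (e < best) best = e;
    }
    A.W[j] = best;
  }
}

// traceback by re-deriving the argmins (tolerance-based)
static void mfe_trace(const std::vector<int>& s, const std::vector<double>& pe,
                      const Model& m, const Arrays& A,
                      std::vector<std::pair<int,int> >& pairs) {
  int n = A.n;
  const double eps = 1e-7;
  std::vector<std::array<int,3> > stack;  // {type,i,j}: 0=E(j) 1=B 2=M 3=M1
  stack.push_back({0, 0, n});
  while (!stack.empty()) {
    auto t = stack.back(); stack.pop_back();
    int type = t[0], i = t[1], j = t[2];
    if (type == 0) {                      // exterior up to j
      while (j >= 1) {
        if (std::fabs(A.W[j] - A.W[j - 1]) < eps) { --j; continue; }
        bool found = false;
        for (int k = 1; k <= j; ++k) {
          double vb = A.B[IDX(k, j)];
          if (vb < INF / 2 && std::fabs(A.W[j] - (A.W[k - 1] + vb)) < eps) {
            stack.push_back({1, k, j});
            j = k - 1; found = true; break;
          }
        }
        if (!found) break;               // numerically ambiguous; stop clean
      }
    } else if (type == 1) {              // B(i,j): emit pair, find its case
      pairs.push_back(std::make_pair(i, j));
      double target = A.B[IDX(i, j)] - pe[i] - pe[j];
      int pij = ptype(s[i], s[j]);
      if (std::fabs(target - (m.ha + m.hb * (j - i - 1))) < eps) continue;
      bool found = false;
      for (int k = i + 1; k <= j - 2 && k - i - 1 <= m.L && !found; ++k) {
        int s1 = k - i - 1;
        for (int l = j - 1; l >= k + m.h + 1; --l) {
          int s2 = j - l - 1;
          if (s1 + s2 > m.L) break;
          double vb = A.B[IDX(k, l)];
          if (vb >= INF / 2) continue;
          int pkl = ptype(s[k], s[l]);
          if (std::fabs(target - (il_energy(m, pij, pkl, s1, s2) + vb)) < eps) {
            stack.push_back({1, k, l}); found = true; break;
          }
        }
      }
      if (found) continue;
      for (int mm = i + 2; mm <= j - 2; ++mm) {
        double a1 = A.M[IDX(i + 1, mm - 1)], a2 = A.M1[IDX(mm, j - 1)];
        if (a1 >= INF / 2 || a2 >= INF / 2) continue;
        if (std::fabs(target - (m.mla + a1 + a2)) < eps) {
          stack.push_back({2, i + 1, mm - 1});
          stack.push_back({3, mm, j - 1});
          found = true; break;
        }
      }
    } else if (type == 3) {              // M1(i,j)
      double target = A.M1[IDX(i, j)];
      for (int l = i + m.h + 1; l <= j; ++l) {
        double vb = A.B[IDX(i, l)];
        if (vb < INF / 2 &&
            std::fabs(target - (vb + m.mlb + m.mlc * (j - l))) < eps) {
          stack.push_back({1, i, l}); break;
        }
      }
    } else {                             // M(i,j)
      double target = A.M[IDX(i, j)];
      bool found = false;
      for (int k = i; k <= j && !found; ++k) {
        double m1 = A.M1[IDX(k, j)];
        if (m1 >= INF / 2) continue;
        if (std::fabs(target - (m.mlc * (k - i) + m1)) < eps) {
          stack.push_back({3, k, j}); found = true;
        } else if (k > i) {
          double mm = A.M[IDX(i, k - 1)];
          if (mm < INF / 2 && std::fabs(target - (mm + m1)) < eps) {
            stack.push_back({2, i, k - 1});
            stack.push_back({3, k, j});
            found = true;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_codes, NumericVector pseudo, List params) {
  Model m = read_model(params);
  int n = seq_codes.size();
  std::vector<int> s(n + 2, -1);
  std::vector<double> pe(n + 2, 0.0);
  for (int i = 1; i <= n; ++i) {
    s[i] = seq_codes[i - 1];
    pe[i] = pseudo[i - 1];
  }
  Arrays A(n);
  mfe_fill(s, pe, m, A);
  std::vector<std::pair<int,int> > pairs;
  mfe_trace(s, pe, m, A, pairs);
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    pm(k, 0) = pairs[k].first; pm(k, 1) = pairs[k].second;
  }
  return List::create(_["energy"] = A.W[n], _["pairs"] = pm);
}

// [[Rcpp::export(name = ".pairprob_cpp")]]
NumericMatrix pairprob_cpp(IntegerVector seq_codes, NumericVector pseudo,
                           List params, double mfe) {
  Model m = read_model(params);
  int n = seq_codes.size();
  std::vector<int> s(n + 2, -1);
  std::vector<double> pe(n + 2, 0.0);
  for (int i = 1; i <= n; ++i) { s[i] = seq_codes[i - 1]; pe[i] = pseudo[i - 1]; }
  double E0 = (mfe < 0 ? mfe : 0.0) / std::max(1, n);
  double u = std::exp(E0 / m.RT);
  auto bw = [&](double e) { return std::exp(-e / m.RT); };

  size_t sz = (size_t)(n + 2) * (n + 2);
  std::vector<double> QB(sz, 0.0), QM(sz, 0.0), QM1(sz, 0.0);
  std::vector<double> OB(sz, 0.0), OM(sz, 0.0), OM1(sz, 0.0);
  std::vector<double> Qp(n + 2, 0.0), Qs(n + 2, 0.0);
  std::vector<double> upow(n + 2, 1.0);
  for (int k = 1; k <= n + 1; ++k) upow[k] = upow[k - 1] * u;

  // ---------- inside ----------
  for (int span = m.h + 1; span <= n - 1; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      int pij = ptype(s[i], s[j]);
      if (pij > 0 && j - i - 1 >= m.h) {
        double tot = bw(m.ha + m.hb * (j - i - 1)) * upow[j - i + 1];
        for (int k = i + 1; k <= j - 2 && k - i - 1 <= m.L; ++k) {
          int s1 = k - i - 1;
          for (int l = j - 1; l >= k + m.h + 1; --l) {
            int s2 = j - l - 1;
            if (s1 + s2 > m.L) break;
            double qb = QB[IDX(k, l)];
            if (qb == 0.0) continue;
            int pkl = ptype(s[k], s[l]);
            tot += bw(il_energy(m, pij, pkl, s1, s2)) *
                   upow[s1 + s2 + 2] * qb;
          }
        }
        double ml = 0.0;
        for (int mm = i + 2; mm <= j - 2; ++mm)
          ml += QM[IDX(i + 1, mm - 1)] * QM1[IDX(mm, j - 1)];
        tot += bw(m.mla) * upow[2] * ml;
        QB[IDX(i, j)] = tot * bw(pe[i] + pe[j]);
      }
      {
        double tot = 0.0;
        for (int l = i + m.h + 1; l <= j; ++l) {
          double qb = QB[IDX(i, l)];
          if (qb > 0.0) tot += qb * bw(m.mlb + m.mlc * (j - l)) * upow[j - l];
        }
        QM1[IDX(i, j)] = tot;
      }
      {
        double tot = 0.0;
        for (int k = i; k <= j; ++k) {
          double m1 = QM1[IDX(k, j)];
          if (m1 == 0.0) continue;
          tot += bw(m.mlc * (k - i)) * upow[k - i] * m1;
          if (k > i) tot += QM[IDX(i, k - 1)] * m1;
        }
        QM[IDX(i, j)] = tot;
      }
    }
  }
  Qp[0] = 1.0;
  for (int j = 1; j <= n; ++j) {
    double tot = Qp[j - 1] * u;
    for (int i = 1; i <= j; ++i)
      if (QB[IDX(i, j)] > 0.0) tot += Qp[i - 1] * QB[IDX(i, j)];
    Qp[j] = tot;
  }
  Qs[n + 1] = 1.0;
  for (int i = n; i >= 1; --i) {
    double tot = Qs[i + 1] * u;
    for (int j = i; j <= n; ++j)
      if (QB[IDX(i, j)] > 0.0) tot += QB[IDX(i, j)] * Qs[j + 1];
    Qs[i] = tot;
  }
  double Qtot = Qp[n];

  // ---------- outside (largest spans first; per span: OM, then OM1, then OB)
  for (int span = n - 1; span >= m.h + 1; --span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      // OM(i,j)
      {
        double tot = 0.0;
        if (i >= 2) {
          int k = i - 1;
          int pk = 0;
          for (int l = j + 2; l <= n; ++l) {
            pk = ptype(s[k], s[l]);
            if (pk == 0) continue;
            double ob = OB[IDX(k, l)];
            if (ob == 0.0) continue;
            tot += ob * bw(m.mla + pe[k] + pe[l]) * upow[2] *
                   QM1[IDX(j + 1, l - 1)];
          }
        }
        for (int j2 = j + 1; j2 <= n; ++j2) {
          double om = OM[IDX(i, j2)];
          if (om == 0.0) continue;
          double m1 = QM1[IDX(j + 1, j2)];
          if (m1 > 0.0) tot += om * m1;
        }
        OM[IDX(i, j)] = tot;
      }
      // OM1(i,j)
      {
        double tot = 0.0;
        for (int i0 = 1; i0 <= i; ++i0) {
          double om = OM[IDX(i0, j)];
          if (om == 0.0) continue;
          tot += om * bw(m.mlc * (i - i0)) * upow[i - i0];
          if (i0 <= i - 1) {
            double qm = QM[IDX(i0, i - 1)];
            if (qm > 0.0) tot += om * qm;
          }
        }
        if (j + 1 <= n) {
          for (int k = 1; k <= i - 2; ++k) {
            int pk = ptype(s[k], s[j + 1]);
            if (pk == 0) continue;
            double ob = OB[IDX(k, j + 1)];
            if (ob == 0.0) continue;
            double qm = QM[IDX(k + 1, i - 1)];
            if (qm > 0.0)
              tot += ob * bw(m.mla + pe[k] + pe[j + 1]) * upow[2] * qm;
          }
        }
        OM1[IDX(i, j)] = tot;
      }
      // OB(i,j)
      if (QB[IDX(i, j)] > 0.0) {
        double tot = Qp[i - 1] * Qs[j + 1];
        int pij = ptype(s[i], s[j]);
        for (int k = i - 1; k >= 1 && i - k - 1 <= m.L; --k) {
          int s1 = i - k - 1;
          for (int l = j + 1; l <= n; ++l) {
            int s2 = l - j - 1;
            if (s1 + s2 > m.L) break;
            int pkl = ptype(s[k], s[l]);
            if (pkl == 0 || l - k - 1 < m.h) continue;
            double ob = OB[IDX(k, l)];
            if (ob == 0.0) continue;
            tot += ob * bw(il_energy(m, pkl, pij, s1, s2) + pe[k] + pe[l]) *
                   upow[s1 + s2 + 2];
          }
        }
        for (int j2 = j; j2 <= n; ++j2) {
          double om1 = OM1[IDX(i, j2)];
          if (om1 == 0.0) continue;
          tot += om1 * bw(m.mlb + m.mlc * (j2 - j)) * upow[j2 - j];
        }
        OB[IDX(i, j)] = tot;
      }
    }
  }

  NumericMatrix P(n, n);
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j) {
      double qb = QB[IDX(i, j)];
      if (qb > 0.0) {
        double p = qb * OB[IDX(i, j)] / Qtot;
        if (p < 0) p = 0;
        if (p > 1) p = 1;
        P(i - 1, j - 1) = p;
      }
    }
  return P;
}
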