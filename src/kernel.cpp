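#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Shannon entropy in bits of a count vector (plug-in / maximum likelihood).
static inline double entropy_bits(const std::vector<double>& counts, double n) {
  double h = 0.0;
  for (double c : counts) {
    if (c > 0.0) {
      double p = c / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// Batch QMDR scorer. For each model (vector of 1-based SNP column indices)
// assigns every sample to its multilocus genotype cell, labels cells high
// when the cell mean trait strictly exceeds the grand mean, pools samples
// into G1 (high) / G0 (low) and computes the pooled two-sample t-statistic
// G1 - G0. Degenerate layouts (either group < 2 samples, or zero pooled
// variance) score t = 0 with valid = 0. The interaction-information
// objective is the mean of the expert-knowledge gains over all unordered
// SNP pairs in the model (0 for single-SNP models).
// Returns an M x 4 matrix: t_statistic, interaction_info, size, valid.
// [[Rcpp::export]]
NumericMatrix qmdr_score_batch_cpp(const IntegerMatrix& geno,
                                   const NumericVector& pheno,
                                   const List& models,
                                   const NumericMatrix& ek_gain) {
  const int n = geno.nrow();
  double grand = 0.0;
  for (int i = 0; i < n; ++i) grand += pheno[i];
  grand /= n;

  const int M = models.size();
  NumericMatrix out(M, 4);
  colnames(out) = CharacterVector::create("t_statistic", "interaction_info",
                                          "size", "valid");

  // Buffers sized for the largest model in the batch, cleared lazily via a
  // touched-cell list so huge mostly-empty 3^K tables cost O(observed).
  int max_ncell = 3;
  for (int m = 0; m < M; ++m) {
    IntegerVector idx = models[m];
    int nc = 1;
    for (int k = 0; k < idx.size(); ++k) nc *= 3;
    if (nc > max_ncell) max_ncell = nc;
  }
  std::vector<int> cell(n), touched;
  touched.reserve(n);
  std::vector<double> cnt(max_ncell, 0.0), sum(max_ncell, 0.0);
  std::vector<char> high(max_ncell, 0);
  std::vector<int> col(16);

  for (int m = 0; m < M; ++m) {
    IntegerVector idx = models[m];
    const int K = idx.size();
    if (static_cast<int>(col.size()) < K) col.resize(K);
    for (int k = 0; k < K; ++k) col[k] = idx[k] - 1;
    touched.clear();

    // column-wise accumulation of cell ids (cache-friendly on the
    // column-major genotype matrix)
    {
      const int* g0 = geno.begin() + static_cast<size_t>(col[0]) * n;
      for (int i = 0; i < n; ++i) cell[i] = g0[i];
      int mult = 3;
      for (int k = 1; k < K; ++k) {
        const int* g = geno.begin() + static_cast<size_t>(col[k]) * n;
        for (int i = 0; i < n; ++i) cell[i] += g[i] * mult;
        mult *= 3;
      }
    }
    for (int i = 0; i < n; ++i) {
      int c = cell[i];
      if (cnt[c] == 0.0) touched.push_back(c);
      cnt[c] += 1.0;
      sum[c] += pheno[i];
    }

    double n1 = 0.0, s1 = 0.0, n0 = 0.0, s0 = 0.0;
    for (int c : touched) {
      if (sum[c] / cnt[c] > grand) {
        high[c] = 1;
        n1 += cnt[c];
        s1 += sum[c];
      } else {
        n0 += cnt[c];
        s0 += sum[c];
      }
    }

    double t = 0.0, valid = 0.0;
    if (n1 >= 2.0 && n0 >= 2.0) {
      const double m1 = s1 / n1, m0 = s0 / n0;
      // second pass: textbook centered sums of squares (numerically stable)
      double ss1 = 0.0, ss0 = 0.0;
      for (int i = 0; i < n; ++i) {
        if (high[cell[i]]) {
          double d = pheno[i] - m1;
          ss1 += d * d;
        } else {
          double d = pheno[i] - m0;
          ss0 += d * d;
        }
      }
      double sp2 = (ss1 + ss0) / (n1 + n0 - 2.0);
      if (sp2 > 0.0) {
        t = (m1 - m0) / std::sqrt(sp2 * (1.0 / n1 + 1.0 / n0));
        valid = 1.0;
      }
    }

    double mii = 0.0;
    if (K >= 2) {
      int np = 0;
      for (int a = 0; a < K; ++a)
        for (int b = a + 1; b < K; ++b) {
          mii += ek_gain(idx[a] - 1, idx[b] - 1);
          ++np;
        }
      mii /= np;
    }

    out(m, 0) = t;
    out(m, 1) = mii;
    out(m, 2) = K;
    out(m, 3) = valid;

    for (int c : touched) {
      cnt[c] = 0.0;
      sum[c] = 0.0;
      high[c] = 0;
    }
  }
  return out;
}

// Canonical cache keys for SNP-set models (sorted indices, comma-joined).
// [[Rcpp::export]]
CharacterVector model_keys_cpp(const List& models) {
  const int M = models.size();
  CharacterVector out(M);
  std::vector<int> v;
  std::string buf;
  for (int m = 0; m < M; ++m) {
    IntegerVector idx = models[m];
    v.assign(idx.begin(), idx.end());
    std::sort(v.begin(), v.end());
    buf.clear();
    for (size_t k = 0; k < v.size(); ++k) {
      if (k) buf.push_back(',');
      buf += std::to_string(v[k]);
    }
    out[m] = buf;
  }
  return out;
}

// Pairwise interaction information (information gain) for all SNP pairs:
// IG(A,B;C) = I(A,B;C) - I(A;C) - I(B;C), plug-in estimates in bits, with
// (A,B) the 9-category joint genotype variable and C a binary class.
// Returns a symmetric n_snps x n_snps matrix with zero diagonal.
// [[Rcpp::export]]
NumericMatrix interaction_gain_matrix_cpp(const IntegerMatrix& geno,
                                          const IntegerVector& cls) {
  const int n = geno.nrow();
  const int m = geno.ncol();
  const double nn = static_cast<double>(n);

  std::vector<double> cC(2, 0.0);
  for (int i = 0; i < n; ++i) cC[cls[i]] += 1.0;
  const double hC = entropy_bits(cC, nn);

  // per-SNP: I(A;C)
  std::vector<double> iAC(m, 0.0);
  for (int j = 0; j < m; ++j) {
    std::vector<double> cA(3, 0.0), cAC(6, 0.0);
    for (int i = 0; i < n; ++i) {
      int g = geno(i, j);
      cA[g] += 1.0;
      cAC[g * 2 + cls[i]] += 1.0;
    }
    iAC[j] = entropy_bits(cA, nn) + hC - entropy_bits(cAC, nn);
  }

  NumericMatrix out(m, m);
  std::vector<double> cAB(9), cABC(18);
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      std::fill(cAB.begin(), cAB.end(), 0.0);
      std::fill(cABC.begin(), cABC.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        int g = geno(i, a) * 3 + geno(i, b);
        cAB[g] += 1.0;
        cABC[g * 2 + cls[i]] += 1.0;
      }
      double iABC = entropy_bits(cAB, nn) + hC - entropy_bits(cABC, nn);
      double gain = iABC - iAC[a] - iAC[b];
      out(a, b) = gain;
      out(b, a) = gain;
    }
  }
  return out;
}

// Fast nondominated sorting (NSGA-II fronts) for the three objectives:
// maximize t, maximize ig, minimize size. Returns 0-based ranks.
// [[Rcpp::export]]
IntegerVector nds_rank_cpp(const NumericVector& t, const NumericVector& ig,
                           const NumericVector& size) {
  const int n = t.size();
  IntegerVector rank(n, -1);
  if (n == 0) return rank;
  std::vector<int> ndom(n, 0);
  std::vector<std::vector<int>> dominates(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool i_ge = t[i] >= t[j] && ig[i] >= ig[j] && size[i] <= size[j];
      bool j_ge = t[j] >= t[i] && ig[j] >= ig[i] && size[j] <= size[i];
      if (i_ge && !j_ge) {
        dominates[i].push_back(j);
        ++ndom[j];
      } else if (j_ge && !i_ge) {
        dominates[j].push_back(i);
        ++ndom[i];
      }
    }
  }
  std::vector<int> front;
  for (int i = 0; i < n; ++i)
    if (ndom[i] == 0) front.push_back(i);
  int r = 0;
  while (!front.empty()) {
    std::vector<int> next;
    for (int i : front) {
      rank[i] = r;
      for (int j : dominates[i])
        if (--ndom[j] == 0) next.push_back(j);
    }
    front.swap(next);
    ++r;
  }
  return rank;
}

// NSGA-II crowding distance for models sharing one front: per objective,
// boundary models get +Inf, interior models accumulate normalized
// neighbour gaps; a zero range contributes 0.
// [[Rcpp::export]]
NumericVector crowding_cpp(const NumericVector& t, const NumericVector& ig,
                           const NumericVector& size) {
  const int n = t.size();
  NumericVector d(n, 0.0);
  if (n == 0) return d;
  std::vector<int> ord(n);
  const NumericVector* objs[3] = {&t, &ig, &size};
  for (int o = 0; o < 3; ++o) {
    const NumericVector& x = *objs[o];
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&x](int a, int b) { return x[a] < x[b]; });
    double rng = x[ord[n - 1]] - x[ord[0]];
    d[ord[0]] = R_PosInf;
    d[ord[n - 1]] = R_PosInf;
    if (n > 2 && rng > 0) {
      for (int k = 1; k < n - 1; ++k) {
        if (d[ord[k]] != R_PosInf)
          d[ord[k]] += (x[ord[k + 1]] - x[ord[k - 1]]) / rng;
      }
    }
  }
  return d;
}

// ---- breeding kernel -----------------------------------------------------
// Generates children for one generation using R's RNG (deterministic under
// set.seed). Mirrors the exported R operator functions: reservoir-sampled
// tournaments (uniform among ties), any-point crossover with keep-first
// dedup / empty-child repair / truncation, and per-SNP mutation.

static inline int runif_int(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static int tour_pars_cpp(const IntegerVector& msize, int npop, int tsize) {
  int best = -1, bestv = 0, nties = 0;
  for (int t = 0; t < tsize; ++t) {
    int e = runif_int(npop);
    int v = msize[e];
    if (best < 0 || v < bestv) {
      best = e; bestv = v; nties = 1;
    } else if (v == bestv) {
      ++nties;
      if (unif_rand() * nties < 1.0) best = e;
    }
  }
  return best;
}

static int tour_rc_cpp(const IntegerVector& rank, const NumericVector& crowd,
                       int npop, int tsize) {
  int best = -1, nties = 0;
  for (int t = 0; t < tsize; ++t) {
    int e = runif_int(npop);
    if (best < 0 || rank[e] < rank[best] ||
        (rank[e] == rank[best] && crowd[e] > crowd[best])) {
      best = e; nties = 1;
    } else if (rank[e] == rank[best] && crowd[e] == crowd[best]) {
      ++nties;
      if (unif_rand() * nties < 1.0) best = e;
    }
  }
  return best;
}

static inline bool contains(const std::vector<int>& v, int x) {
  return std::find(v.begin(), v.end(), x) != v.end();
}

static void mutate_cpp(std::vector<int>& m, int n_snps, double rate) {
  if (rate <= 0.0) return;
  for (size_t j = 0; j < m.size(); ++j) {
    if (unif_rand() < rate) {
      if (static_cast<int>(m.size()) >= n_snps) break;
      int cand;
      do {
        cand = runif_int(n_snps) + 1;
      } while (contains(m, cand));
      m[j] = cand;
    }
  }
}

static void crossover_cpp(const std::vector<int>& a, const std::vector<int>& b,
                          int max_size, std::vector<int>& c1,
                          std::vector<int>& c2) {
  const int la = a.size(), lb = b.size();
  const int ca = runif_int(la + 1), cb = runif_int(lb + 1);
  c1.clear(); c2.clear();
  for (int i = 0; i < ca; ++i)
    if (!contains(c1, a[i])) c1.push_back(a[i]);
  for (int i = cb; i < lb; ++i)
    if (!contains(c1, b[i])) c1.push_back(b[i]);
  for (int i = 0; i < cb; ++i)
    if (!contains(c2, b[i])) c2.push_back(b[i]);
  for (int i = ca; i < la; ++i)
    if (!contains(c2, a[i])) c2.push_back(a[i]);
  std::vector<int>* kids[2] = {&c1, &c2};
  for (auto* kid : kids) {
    if (kid->empty()) {
      int pick = runif_int(la + lb);
      kid->push_back(pick < la ? a[pick] : b[pick - la]);
    }
    if (static_cast<int>(kid->size()) > max_size) kid->resize(max_size);
  }
}

// [[Rcpp::export]]
List breed_children_cpp(const List& models, const IntegerVector& rank,
                        const NumericVector& crowd, const IntegerVector& msize,
                        int n_children, int n_snps, double p_cross,
                        double mut_rate, int tsize_pars, int tsize_rank,
                        int max_size, bool client_mode) {
  const int npop = models.size();
  std::vector<std::vector<int>> pop(npop);
  for (int i = 0; i < npop; ++i) {
    IntegerVector v = models[i];
    pop[i].assign(v.begin(), v.end());
  }
  List out(n_children);
  int nc = 0;
  std::vector<int> c1, c2, buf;
  while (nc < n_children) {
    if (client_mode) {
      // steady-state client rule: two rank/crowding tournaments, second
      // winner mutated, then any-point crossover
      int p1 = tour_rc_cpp(rank, crowd, npop, tsize_rank);
      int p2 = tour_rc_cpp(rank, crowd, npop, tsize_rank);
      buf = pop[p2];
      mutate_cpp(buf, n_snps, mut_rate);
      crossover_cpp(pop[p1], buf, max_size, c1, c2);
      out[nc++] = IntegerVector(c1.begin(), c1.end());
      if (nc < n_children) out[nc++] = IntegerVector(c2.begin(), c2.end());
    } else if (unif_rand() < p_cross) {
      // task rule: parsimony tournament x rank/crowding tournament
      int p1 = tour_pars_cpp(msize, npop, tsize_pars);
      int p2 = tour_rc_cpp(rank, crowd, npop, tsize_rank);
      crossover_cpp(pop[p1], pop[p2], max_size, c1, c2);
      out[nc++] = IntegerVector(c1.begin(), c1.end());
      if (nc < n_children) out[nc++] = IntegerVector(c2.begin(), c2.end());
    } else {
      // task rule: mutate a uniformly drawn model
      buf = pop[runif_int(npop)];
      mutate_cpp(buf, n_snps, mut_rate);
      out[nc++] = IntegerVector(buf.begin(), buf.end());
    }
  }
  return out;
}

// One-call NSGA-II ranking: fronts plus per-front crowding distances.
// [[Rcpp::export]]
List rank_and_crowd_cpp(const NumericVector& t, const NumericVector& ig,
                        const NumericVector& size) {
  const int n = t.size();
  IntegerVector rank = nds_rank_cpp(t, ig, size);
  NumericVector crowd(n);
  int maxr = -1;
  for (int i = 0; i < n; ++i) maxr = std::max(maxr, rank[i]);
  std::vector<int> members;
  for (int r = 0; r <= maxr; ++r) {
    members.clear();
    for (int i = 0; i < n; ++i)
      if (rank[i] == r) members.push_back(i);
    const int m = members.size();
    NumericVector ft(m), fig(m), fsz(m);
    for (int k = 0; k < m; ++k) {
      ft[k] = t[members[k]];
      fig[k] = ig[members[k]];
      fsz[k] = size[members[k]];
    }
    NumericVector d = crowding_cpp(ft, fig, fsz);
    for (int k = 0; k < m; ++k) crowd[members[k]] = d[k];
  }
  return List::create(_["rank"] = rank, _["crowding"] = crowd);
}

// Environmental-selection order: indices (1-based) of the `keep` models
// with lowest rank, ties by highest crowding (stable).
// [[Rcpp::export]]
IntegerVector truncate_idx_cpp(const IntegerVector& rank,
                               const NumericVector& crowd, int keep) {
  const int n = rank.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (rank[a] != rank[b]) return rank[a] < rank[b];
    return crowd[a] > crowd[b];
  });
  if (keep > n) keep = n;
  IntegerVector out(keep);
  for (int i = 0; i < keep; ++i) out[i] = ord[i] + 1;
  return out;
}
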