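// Coalescent machinery for the four-population divergence/admixture scenarios
// and the microsatellite mutation layers (strict SMM and generalized SMM).
//
// Time runs backwards in generations (continuous-time Kingman approximation:
// pairwise coalescence rate 1/(2N) per generation for diploid N). All
// randomness goes through R's RNG, so a single R-level set.seed() makes every
// simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Genealogy {
  std::vector<int> parent;     // parent index per node, -1 at the root
  std::vector<double> time;    // node time in generations (leaves at 0)
  std::vector<int> leaf_pop;   // sampled population per leaf
  int n_leaves;
};

// One realisation of the structured coalescent for a scenario built from the
// three divergence/admixture hypotheses (populations 0=Thrace, 1=West,
// 2=East, 3=Central Anatolia; East carries the ancestral lineage).
Genealogy sim_genealogy(int hyp, const double N[4], double t1, double t2,
                        double t3, double ra, const int ss[4]) {
  int n = ss[0] + ss[1] + ss[2] + ss[3];
  Genealogy g;
  g.n_leaves = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);
  g.leaf_pop.reserve(n);

  std::vector<std::vector<int> > act(4);
  int id = 0;
  for (int p = 0; p < 4; ++p)
    for (int i = 0; i < ss[p]; ++i) {
      act[p].push_back(id);
      g.leaf_pop.push_back(p);
      ++id;
    }

  // event schedule (times must already satisfy t1 < t2 < t3 where used)
  std::vector<double> ev_t;
  std::vector<int> ev_a;  // 0: admixture CA->W/E; 1: W->E; 2: T->E; 3: T->W
  ev_t.push_back(t1); ev_a.push_back(0);
  if (hyp == 1) {
    ev_t.push_back(t2); ev_a.push_back(1);
    ev_t.push_back(t3); ev_a.push_back(2);
  } else if (hyp == 2) {
    ev_t.push_back(t3); ev_a.push_back(1);
    ev_t.push_back(t3); ev_a.push_back(2);
  } else if (hyp == 3) {
    ev_t.push_back(t2); ev_a.push_back(3);
    ev_t.push_back(t3); ev_a.push_back(1);
  } else {
    stop("unknown hypothesis id");
  }

  double t = 0.0;
  int next_node = n;
  int alive = n;
  size_t ev = 0;

  while (alive > 1) {
    double te = (ev < ev_t.size()) ? ev_t[ev] : R_PosInf;
    // coalesce within populations until the next demographic event
    while (alive > 1) {
      double rate = 0.0, rp[4];
      for (int p = 0; p < 4; ++p) {
        double k = (double)act[p].size();
        rp[p] = (k > 1) ? k * (k - 1.0) / 2.0 / (2.0 * N[p]) : 0.0;
        rate += rp[p];
      }
      if (rate <= 0.0) {
        if (!R_FINITE(te)) stop("stranded lineages: scenario has no root");
        break;
      }
      double dt = R::rexp(1.0 / rate);
      if (t + dt >= te) break;
      t += dt;
      double u = R::runif(0.0, rate), acc = 0.0;
      int p = 3;
      for (int q = 0; q < 4; ++q) { acc += rp[q]; if (u <= acc) { p = q; break; } }
      int k = (int)act[p].size();
      int i = (int)std::floor(R::runif(0.0, k)); if (i >= k) i = k - 1;
      int j = (int)std::floor(R::runif(0.0, k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = act[p][i], b = act[p][j];
      g.parent[a] = next_node; g.parent[b] = next_node;
      g.time[next_node] = t;
      if (i > j) std::swap(i, j);
      act[p].erase(act[p].begin() + j);
      act[p][i] = next_node;
      ++next_node; --alive;
    }
    if (alive > 1 && ev < ev_t.size()) {
      t = ev_t[ev];
      int a = ev_a[ev];
      if (a == 0) {  // CA lineages trace back to West with prob ra, else East
        for (size_t i = 0; i < act[3].size(); ++i) {
          int dest = (R::unif_rand() < ra) ? 1 : 2;
          act[dest].push_back(act[3][i]);
        }
        act[3].clear();
      } else if (a == 1) { act[2].insert(act[2].end(), act[1].begin(), act[1].end()); act[1].clear(); }
      else if (a == 2)   { act[2].insert(act[2].end(), act[0].begin(), act[0].end()); act[0].clear(); }
      else               { act[1].insert(act[1].end(), act[0].begin(), act[0].end()); act[0].clear(); }
      ++ev;
    }
  }
  return g;
}

inline int reflect_allele(int a, int amin, int amax) {
  while (a < amin || a > amax) {
    if (a < amin) a = 2 * amin - a;
    else a = 2 * amax - a;
  }
  return a;
}

// Drop stepwise mutations on every branch; GSM step length 1 + Geometric(P)
// (strict SMM when P = 0), symmetric direction, reflected at the bounds.
void mutate_tree(const Genealogy &g, double mu, double P, int root_allele,
                 int amin, int amax, std::vector<int> &allele) {
  int m = (int)g.parent.size();
  allele.assign(m, root_allele);
  for (int node = m - 2; node >= 0; --node) {
    int par = g.parent[node];
    double len = g.time[par] - g.time[node];
    int a = allele[par];
    int nm = (int)R::rpois(mu * len);
    for (int k = 0; k < nm; ++k) {
      int step = 1;
      if (P > 0.0) step += (int)R::rgeom(1.0 - P);
      if (R::unif_rand() < 0.5) step = -step;
      a = reflect_allele(a + step, amin, amax);
    }
    allele[node] = a;
  }
}

// One multi-locus diploid dataset: independent genealogy and mutations per
// locus; rows are gene copies (two consecutive rows per individual),
// population-major in the order Thrace, West, East, Central Anatolia.
IntegerMatrix sim_dataset(int hyp, const double N[4], double t1, double t2,
                          double t3, double ra, double mu, double P,
                          int n_loci, const int ss_ind[4], int amin, int amax,
                          int root_allele) {
  int ss[4];
  int n_ind = 0;
  for (int p = 0; p < 4; ++p) { ss[p] = 2 * ss_ind[p]; n_ind += ss_ind[p]; }
  IntegerMatrix out(2 * n_ind, n_loci);
  std::vector<int> allele;
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = sim_genealogy(hyp, N, t1, t2, t3, ra, ss);
    mutate_tree(g, mu, P, root_allele, amin, amax, allele);
    for (int i = 0; i < 2 * n_ind; ++i) out(i, l) = allele[i];
  }
  return out;
}

// 30 default summary statistics for 4 groups:
//   per group (x4): mean number of alleles, mean unbiased expected
//   heterozygosity, mean allele-size variance (12 one-sample statistics);
//   per pair (x6): multi-locus Weir-Cockerham theta, mean shared-allele
//   distance, mean (delta-mu)^2 (18 two-sample statistics).
// Allele value 0 encodes a missing gene copy and is skipped.
NumericVector summary_stats(const IntegerMatrix &alleles,
                            const IntegerVector &gsize_ind) {
  int n_loci = alleles.ncol();
  int G = gsize_ind.size();
  std::vector<int> row0(G);  // first gene-copy row of each group
  int r = 0;
  for (int g = 0; g < G; ++g) { row0[g] = r; r += 2 * gsize_ind[g]; }

  NumericVector out(12 + 18);
  // one-sample statistics
  for (int g = 0; g < G; ++g) {
    double s_nal = 0, s_he = 0, s_var = 0;
    int n_nal = 0, n_he = 0, n_var = 0;
    for (int l = 0; l < n_loci; ++l) {
      std::map<int, int> cnt;
      int nc = 0; double sum = 0, sum2 = 0;
      for (int i = 0; i < 2 * gsize_ind[g]; ++i) {
        int a = alleles(row0[g] + i, l);
        if (a == 0) continue;
        ++cnt[a]; ++nc; sum += a; sum2 += (double)a * a;
      }
      if (nc >= 1) { s_nal += (double)cnt.size(); ++n_nal; }
      if (nc >= 2) {
        double sp2 = 0;
        for (std::map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it) {
          double p = (double)it->second / nc;
          sp2 += p * p;
        }
        s_he += (double)nc / (nc - 1.0) * (1.0 - sp2); ++n_he;
        double v = (sum2 - sum * sum / nc) / (nc - 1.0);
        s_var += v; ++n_var;
      }
    }
    out[g]         = n_nal ? s_nal / n_nal : NA_REAL;
    out[G + g]     = n_he  ? s_he  / n_he  : NA_REAL;
    out[2 * G + g] = n_var ? s_var / n_var : NA_REAL;
  }

  int pos = 3 * G;
  int n_pairs = G * (G - 1) / 2;
  int pi = 0;
  for (int g = 0; g < G; ++g) for (int h = g + 1; h < G; ++h, ++pi) {
    double sum_a = 0, sum_abc = 0;      // Weir-Cockerham components
    double das_sum = 0; long das_n = 0; // shared-allele distance
    double dmu_sum = 0; int dmu_n = 0;  // (delta-mu)^2
    for (int l = 0; l < n_loci; ++l) {
      // individuals fully scored at this locus
      std::vector<int> ig, ih;
      for (int i = 0; i < gsize_ind[g]; ++i) {
        int a1 = alleles(row0[g] + 2 * i, l), a2 = alleles(row0[g] + 2 * i + 1, l);
        if (a1 != 0 && a2 != 0) ig.push_back(i);
      }
      for (int j = 0; j < gsize_ind[h]; ++j) {
        int a1 = alleles(row0[h] + 2 * j, l), a2 = alleles(row0[h] + 2 * j + 1, l);
        if (a1 != 0 && a2 != 0) ih.push_back(j);
      }
      int n1 = (int)ig.size(), n2 = (int)ih.size();
      // (delta-mu)^2 and Das need at least one individual each
      if (n1 >= 1 && n2 >= 1) {
        double m1 = 0, m2 = 0;
        for (int ii = 0; ii < n1; ++ii)
          m1 += alleles(row0[g] + 2 * ig[ii], l) + alleles(row0[g] + 2 * ig[ii] + 1, l);
        for (int jj = 0; jj < n2; ++jj)
          m2 += alleles(row0[h] + 2 * ih[jj], l) + alleles(row0[h] + 2 * ih[jj] + 1, l);
        m1 /= 2.0 * n1; m2 /= 2.0 * n2;
        dmu_sum += (m1 - m2) * (m1 - m2); ++dmu_n;
        std::vector<int> ya(2 * n2);
        for (int jj = 0; jj < n2; ++jj) {
          ya[2 * jj] = alleles(row0[h] + 2 * ih[jj], l);
          ya[2 * jj + 1] = alleles(row0[h] + 2 * ih[jj] + 1, l);
        }
        for (int ii = 0; ii < n1; ++ii) {
          int x1 = alleles(row0[g] + 2 * ig[ii], l), x2 = alleles(row0[g] + 2 * ig[ii] + 1, l);
          for (int jj = 0; jj < n2; ++jj) {
            int y1 = ya[2 * jj], y2 = ya[2 * jj + 1];
            // proportion of shared alleles via min-count matching
            int shared = 0;
            bool u1 = false, u2 = false;
            if (x1 == y1)      { ++shared; u1 = true; }
            else if (x1 == y2) { ++shared; u2 = true; }
            if (x2 == y1 && !u1)      ++shared;
            else if (x2 == y2 && !u2) ++shared;
            das_sum += 1.0 - shared / 2.0; ++das_n;
          }
        }
      }
      if (n1 < 2 || n2 < 2) continue;  // WC needs variance within both
      // per allele: gene-copy counts and heterozygote-carrier counts
      std::map<int, int> cg, ch, hg, hh;
      for (int ii = 0; ii < n1; ++ii) {
        int x1 = alleles(row0[g] + 2 * ig[ii], l), x2 = alleles(row0[g] + 2 * ig[ii] + 1, l);
        ++cg[x1]; ++cg[x2];
        if (x1 != x2) { ++hg[x1]; ++hg[x2]; }
      }
      for (int jj = 0; jj < n2; ++jj) {
        int y1 = alleles(row0[h] + 2 * ih[jj], l), y2 = alleles(row0[h] + 2 * ih[jj] + 1, l);
        ++ch[y1]; ++ch[y2];
        if (y1 != y2) { ++hh[y1]; ++hh[y2]; }
      }
      std::map<int, bool> all_alleles;
      for (std::map<int,int>::iterator it = cg.begin(); it != cg.end(); ++it) all_alleles[it->first] = true;
      for (std::map<int,int>::iterator it = ch.begin(); it != ch.end(); ++it) all_alleles[it->first] = true;
      if (all_alleles.size() < 2) continue;  // monomorphic across the pair
      double nbar = (n1 + n2) / 2.0;
      double nc2 = ((double)(n1 + n2) -
                    ((double)n1 * n1 + (double)n2 * n2) / (n1 + n2));
      if (nbar <= 1.0 || nc2 <= 0.0) continue;
      for (std::map<int,bool>::iterator it = all_alleles.begin(); it != all_alleles.end(); ++it) {
        int A = it->first;
        double p1 = (cg.count(A) ? cg[A] : 0) / (2.0 * n1);
        double p2 = (ch.count(A) ? ch[A] : 0) / (2.0 * n2);
        double h1 = (hg.count(A) ? hg[A] : 0) / (double)n1;
        double h2 = (hh.count(A) ? hh[A] : 0) / (double)n2;
        double pbar = (n1 * p1 + n2 * p2) / (double)(n1 + n2);
        double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                     n2 * (p2 - pbar) * (p2 - pbar)) / nbar;
        double hbar = (n1 * h1 + n2 * h2) / (double)(n1 + n2);
        double a = nbar / nc2 *
          (s2 - (pbar * (1 - pbar) - s2 / 2.0 - hbar / 4.0) / (nbar - 1.0));
        double b = nbar / (nbar - 1.0) *
          (pbar * (1 - pbar) - s2 / 2.0 - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
        double c = hbar / 2.0;
        sum_a += a; sum_abc += a + b + c;
      }
    }
    out[pos + pi]              = (sum_abc > 0) ? sum_a / sum_abc : NA_REAL;
    out[pos + n_pairs + pi]    = das_n ? das_sum / das_n : NA_REAL;
    out[pos + 2 * n_pairs + pi] = dmu_n ? dmu_sum / dmu_n : NA_REAL;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List sim_genealogy_cpp(int hyp, NumericVector N, double t1, double t2,
                       double t3, double ra, IntegerVector sample_copies) {
  if (N.size() != 4 || sample_copies.size() != 4)
    stop("N and sample_copies must have length 4");
  double Nn[4]; int ss[4];
  for (int i = 0; i < 4; ++i) { Nn[i] = N[i]; ss[i] = sample_copies[i]; }
  Genealogy g = sim_genealogy(hyp, Nn, t1, t2, t3, ra, ss);
  return List::create(_["parent"] = wrap(g.parent), _["time"] = wrap(g.time),
                      _["leaf_pop"] = wrap(g.leaf_pop),
                      _["n_leaves"] = g.n_leaves);
}

// [[Rcpp::export]]
IntegerVector mutate_msat_cpp(IntegerVector parent, NumericVector time,
                              int n_leaves, double mu, double P,
                              int root_allele, int amin, int amax) {
  Genealogy g;
  g.parent.assign(parent.begin(), parent.end());
  g.time.assign(time.begin(), time.end());
  g.n_leaves = n_leaves;
  std::vector<int> allele;
  mutate_tree(g, mu, P, root_allele, amin, amax, allele);
  return IntegerVector(allele.begin(), allele.begin() + n_leaves);
}

// [[Rcpp::export]]
IntegerMatrix sim_msat_dataset_cpp(int hyp, NumericVector N, double t1,
                                   double t2, double t3, double ra, double mu,
                                   double P, int n_loci,
                                   IntegerVector sample_ind, int amin,
                                   int amax, int root_allele) {
  double Nn[4]; int ss[4];
  for (int i = 0; i < 4; ++i) { Nn[i] = N[i]; ss[i] = sample_ind[i]; }
  return sim_dataset(hyp, Nn, t1, t2, t3, ra, mu, P, n_loci, ss, amin, amax,
                     root_allele);
}

// [[Rcpp::export]]
NumericVector summary_stats_cpp(IntegerMatrix alleles, IntegerVector gsize_ind) {
  return summary_stats(alleles, gsize_ind);
}

// [[Rcpp::export]]
NumericMatrix ref_table_cpp(int hyp, NumericMatrix params,
                            IntegerVector sample_ind, int n_loci, int amin,
                            int amax, int root_allele, int max_retry,
                            double missing_rate) {
  // params columns: N_T, N_W, N_E, N_C, t1, t2, t3, ra, mu, P
  int n = params.nrow();
  NumericMatrix out(n, 30);
  double Nn[4]; int ss[4];
  for (int i = 0; i < 4; ++i) ss[i] = sample_ind[i];
  for (int i = 0; i < n; ++i) {
    for (int tr = 0; tr <= max_retry; ++tr) {
      for (int q = 0; q < 4; ++q) Nn[q] = params(i, q);
      IntegerMatrix d = sim_dataset(hyp, Nn, params(i, 4), params(i, 5),
                                    params(i, 6), params(i, 7), params(i, 8),
                                    params(i, 9), n_loci, ss, amin, amax,
                                    root_allele);
      if (missing_rate > 0.0) {
        // emulate the observation process: whole genotypes drop out
        int n_ind = d.nrow() / 2;
        for (int ii = 0; ii < n_ind; ++ii)
          for (int l = 0; l < n_loci; ++l)
            if (R::unif_rand() < missing_rate) {
              d(2 * ii, l) = 0; d(2 * ii + 1, l) = 0;
            }
      }
      NumericVector s = summary_stats(d, sample_ind);
      bool ok = true;
      for (int j = 0; j < 30; ++j) if (!R_FINITE(s[j])) { ok = false; break; }
      if (ok || tr == max_retry) {
        for (int j = 0; j < 30; ++j) out(i, j) = s[j];
        break;
      }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
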