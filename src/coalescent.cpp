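// Discrete-generation coalescent with deme founding events and a
// generalized stepwise microsatellite mutation model, plus the ABC
// summary statistics.  Uses R's RNG throughout so set.seed() controls
// all randomness.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One Wright-Fisher generation backward in time for one deme: each
// lineage draws a parent among 2*Ne gene copies; lineages sharing a
// parent coalesce (multiple mergers allowed).
static void wf_generation(std::vector<int>& act, double two_ne, double t,
                          std::vector<double>& ntime,
                          std::vector<int>& nparent) {
  int k = (int)act.size();
  static std::vector<std::pair<long, int> > buf;
  buf.clear();
  buf.reserve(k);
  for (int i = 0; i < k; ++i) {
    long par = (long)std::floor(unif_rand() * two_ne);
    if (par >= (long)two_ne) par = (long)two_ne - 1;
    buf.push_back(std::make_pair(par, act[i]));
  }
  std::sort(buf.begin(), buf.end());
  act.clear();
  int i = 0;
  while (i < k) {
    int j = i + 1;
    while (j < k && buf[j].first == buf[i].first) ++j;
    if (j - i == 1) {
      act.push_back(buf[i].second);
    } else {
      int node = (int)ntime.size();
      ntime.push_back(t);
      nparent.push_back(-1);
      for (int c = i; c < j; ++c) nparent[buf[c].second] = node;
      act.push_back(node);
    }
    i = j;
  }
}

// Merge one random pair of lineages at time t.
static void merge_pair(std::vector<int>& act, double t,
                       std::vector<double>& ntime,
                       std::vector<int>& nparent) {
  int n = (int)act.size();
  int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
  int j = (int)(unif_rand() * (n - 1)); if (j >= n - 1) j = n - 2;
  if (j >= i) ++j;
  int node = (int)ntime.size();
  ntime.push_back(t);
  nparent.push_back(-1);
  nparent[act[i]] = node;
  nparent[act[j]] = node;
  act[i] = node;
  act[j] = act.back();
  act.pop_back();
}

// Evolve one deme's lineages over (t_start, t_end].  Three regimes:
// exact WF parent sampling when lineage numbers are comparable to the
// number of gene copies (bottlenecks: multiple and multi-way mergers
// matter); a per-generation Poisson number of pairwise mergers when the
// per-generation coalescence rate is appreciable but k << 2Ne; and
// geometric waiting-time jumps when the rate is small.
static void evolve_deme(std::vector<int>& act, double two_ne,
                        double t_start, double t_end,
                        std::vector<double>& ntime,
                        std::vector<int>& nparent) {
  double t = t_start;
  while ((int)act.size() >= 2 && t < t_end) {
    double k = (double)act.size();
    double rate = k * (k - 1.0) / (2.0 * two_ne);
    if (k > 0.25 * two_ne) {
      t += 1.0;
      wf_generation(act, two_ne, t, ntime, nparent);
    } else if (rate > 0.1) {
      t += 1.0;
      int m = (int)R::rpois(rate);
      if (m > (int)act.size() - 1) m = (int)act.size() - 1;
      for (int e = 0; e < m; ++e) merge_pair(act, t, ntime, nparent);
    } else {
      double w = 1.0 + R::rgeom(rate);
      if (t + w > t_end) break;
      t += w;
      int n = (int)act.size();
      int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
      int j = (int)(unif_rand() * (n - 1)); if (j >= n - 1) j = n - 2;
      if (j >= i) ++j;
      int node = (int)ntime.size();
      ntime.push_back(t);
      nparent.push_back(-1);
      nparent[act[i]] = node;
      nparent[act[j]] = node;
      act[i] = node;
      act.erase(act.begin() + j);
    }
  }
}

// Simulate diploid microsatellite genotypes under a dated deme-founding
// demography.
//
// deme_of_leaf: 0-based deme per gene copy (leaf), length = 2 * n_ind.
// ne:           diploid effective size per deme (sampled + ancestral).
// events:       rows (time, from, to1, to2, p1), ascending in time; at
//               `time` every lineage in `from` moves to to1 with
//               probability p1, else to to2 (to2 = -1: all to to1).
// final_deme:   deme holding all lineages after the last event.
// mu:           per-locus mutation rates; gsm_p: geometric parameter of
//               the step-size distribution (0 = strict stepwise).
// Returns leaves x n_loci allele sizes (repeat units).
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_alleles(IntegerVector deme_of_leaf,
                                   NumericVector ne, NumericMatrix events,
                                   int final_deme, int n_loci,
                                   NumericVector mu, double gsm_p,
                                   int root_allele, int min_allele) {
  int n_leaves = deme_of_leaf.size();
  int n_demes = ne.size();
  int n_events = events.nrow();
  IntegerMatrix out(n_leaves, n_loci);
  double t_last = n_events ? events(n_events - 1, 0) : 0.0;
  double max_ne = 0.0;
  for (int d = 0; d < n_demes; ++d) if (ne[d] > max_ne) max_ne = ne[d];
  double t_cap = t_last + 400.0 * max_ne + 10000.0;

  for (int l = 0; l < n_loci; ++l) {
    std::vector<double> ntime(n_leaves, 0.0);
    std::vector<int> nparent(n_leaves, -1);
    std::vector<std::vector<int> > act(n_demes);
    for (int i = 0; i < n_leaves; ++i)
      act[deme_of_leaf[i]].push_back(i);

    double t_cur = 0.0;
    for (int e = 0; e < n_events; ++e) {
      double te = events(e, 0);
      if (te > t_cur) {
        for (int d = 0; d < n_demes; ++d)
          if (act[d].size() >= 2)
            evolve_deme(act[d], 2.0 * ne[d], t_cur, te, ntime, nparent);
        t_cur = te;
      }
      int from = (int)events(e, 1);
      int to1 = (int)events(e, 2);
      int to2 = (int)events(e, 3);
      double p1 = events(e, 4);
      for (size_t i = 0; i < act[from].size(); ++i) {
        int dst = (to2 < 0 || unif_rand() < p1) ? to1 : to2;
        act[dst].push_back(act[from][i]);
      }
      act[from].clear();
    }
    // all remaining lineages must be in the final deme
    int total = 0;
    for (int d = 0; d < n_demes; ++d) {
      if (d != final_deme && !act[d].empty())
        stop("stranded lineage in deme %d (no route to the root deme)", d);
      total += (int)act[d].size();
    }
    evolve_deme(act[final_deme], 2.0 * ne[final_deme], t_cur, t_cap,
                ntime, nparent);
    if (act[final_deme].size() != 1)
      stop("coalescent did not reach a single ancestor within the time cap");

    // mutations root -> leaves, nodes in decreasing time order
    int n_nodes = (int)ntime.size();
    std::vector<int> ord(n_nodes);
    for (int i = 0; i < n_nodes; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return ntime[a] > ntime[b];
    });
    std::vector<int> allele(n_nodes, root_allele);
    for (int oi = 0; oi < n_nodes; ++oi) {
      int node = ord[oi];
      int par = nparent[node];
      if (par < 0) continue;
      double br = ntime[par] - ntime[node];
      int a = allele[par];
      int nm = (int)R::rpois(mu[l] * br);
      for (int m = 0; m < nm; ++m) {
        int step = 1 + (gsm_p > 0.0 ? (int)R::rgeom(1.0 - gsm_p) : 0);
        a += (unif_rand() < 0.5) ? step : -step;
        if (a < min_allele) a = min_allele;
      }
      allele[node] = a;
    }
    for (int i = 0; i < n_leaves; ++i) out(i, l) = allele[i];
  }
  return out;
}

// Pairwise coalescence times of two lineages in a single deme of diploid
// size ne (geometric with mean 2*ne, the discrete-generation law).
// [[Rcpp::export]]
NumericVector cpp_pair_coal_times(double ne, int n_draws) {
  NumericVector out(n_draws);
  double p = 1.0 / (2.0 * ne);
  for (int i = 0; i < n_draws; ++i) out[i] = 1.0 + R::rgeom(p);
  return out;
}

// ---------------------------------------------------------------------------
// Summary statistics
// ---------------------------------------------------------------------------

// alleles: n_ind x (2*n_loci), 0 = missing; pop: 0-based labels.
// variant 0 (abc): per-pop mean He (unbiased), per-pop mean
//   Garza-Williamson M, per ordered pop pair the classification index
//   (leave-one-out mean individual log-likelihood difference with
//   Rannala-Mountain Dirichlet-1/K frequency estimates).
// variant 1 (model_check): per-pop mean allele number, per-pop mean
//   allele size variance, per unordered pair shared-allele distance and
//   (delta mu)^2.
// [[Rcpp::export]]
NumericVector cpp_summary_stats(IntegerMatrix alleles, IntegerVector pop,
                                int n_pops, int variant) {
  int n_ind = alleles.nrow();
  int n_loci = alleles.ncol() / 2;

  if (variant == 0) {
    std::vector<double> he(n_pops, 0.0), gwm(n_pops, 0.0);
    std::vector<int> he_n(n_pops, 0), gwm_n(n_pops, 0);
    // classification index accumulators
    std::vector<double> ci(n_pops * n_pops, 0.0);
    std::vector<int> ci_n(n_pops, 0);
    std::vector<double> own_ll(n_ind, 0.0);
    std::vector<double> other_ll(n_ind * n_pops, 0.0);

    for (int l = 0; l < n_loci; ++l) {
      int c1 = 2 * l, c2 = 2 * l + 1;
      // distinct alleles at this locus across the whole dataset
      std::unordered_map<int, int> aidx;
      for (int i = 0; i < n_ind; ++i) {
        int a = alleles(i, c1), b = alleles(i, c2);
        if (a > 0 && !aidx.count(a)) { int k = aidx.size(); aidx[a] = k; }
        if (b > 0 && !aidx.count(b)) { int k = aidx.size(); aidx[b] = k; }
      }
      int K = (int)aidx.size();
      if (K == 0) continue;
      std::vector<double> cnt(n_pops * K, 0.0);
      std::vector<double> ncop(n_pops, 0.0);
      for (int i = 0; i < n_ind; ++i) {
        int a = alleles(i, c1), b = alleles(i, c2);
        if (a <= 0) continue;
        int p = pop[i];
        cnt[p * K + aidx[a]] += 1.0;
        cnt[p * K + aidx[b]] += 1.0;
        ncop[p] += 2.0;
      }
      // per-pop He and M
      for (int p = 0; p < n_pops; ++p) {
        double n2 = ncop[p];
        if (n2 < 2) continue;
        double sump2 = 0.0;
        int na = 0, amin = 0, amax = 0;
        for (std::unordered_map<int, int>::iterator it = aidx.begin();
             it != aidx.end(); ++it) {
          double c = cnt[p * K + it->second];
          if (c > 0) {
            double pr = c / n2;
            sump2 += pr * pr;
            if (na == 0 || it->first < amin) amin = it->first;
            if (na == 0 || it->first > amax) amax = it->first;
            ++na;
          }
        }
        he[p] += n2 / (n2 - 1.0) * (1.0 - sump2);
        he_n[p] += 1;
        gwm[p] += (double)na / (double)(amax - amin + 1);
        gwm_n[p] += 1;
      }
      // per-individual genotype log-likelihoods vs every population
      double prior = 1.0 / (double)K;
      for (int i = 0; i < n_ind; ++i) {
        int a = alleles(i, c1), b = alleles(i, c2);
        if (a <= 0) continue;
        int ia = aidx[a], ib = aidx[b];
        int pi = pop[i];
        for (int q = 0; q < n_pops; ++q) {
          double ca = cnt[q * K + ia], cb = cnt[q * K + ib], n2 = ncop[q];
          if (q == pi) {
            // leave-one-out: remove the focal individual's two copies
            if (ia == ib) ca -= 2.0; else { ca -= 1.0; cb -= 1.0; }
            n2 -= 2.0;
          }
          double ll;
          if (ia == ib) {
            double pa = (ca + prior) / (n2 + 1.0);
            ll = 2.0 * std::log(pa);
          } else {
            double pa = (ca + prior) / (n2 + 1.0);
            double pb = (cb + prior) / (n2 + 1.0);
            ll = std::log(2.0 * pa * pb);
          }
          if (q == pi) own_ll[i] += ll;
          else other_ll[i * n_pops + q] += ll;
        }
      }
    }
    for (int i = 0; i < n_ind; ++i) ci_n[pop[i]] += 1;
    for (int i = 0; i < n_ind; ++i) {
      int pi = pop[i];
      for (int q = 0; q < n_pops; ++q) {
        if (q == pi) continue;
        ci[pi * n_pops + q] += own_ll[i] - other_ll[i * n_pops + q];
      }
    }
    NumericVector out(2 * n_pops + n_pops * (n_pops - 1));
    int pos = 0;
    for (int p = 0; p < n_pops; ++p)
      out[pos++] = he_n[p] ? he[p] / he_n[p] : 0.0;
    for (int p = 0; p < n_pops; ++p)
      out[pos++] = gwm_n[p] ? gwm[p] / gwm_n[p] : 0.0;
    for (int p = 0; p < n_pops; ++p)
      for (int q = 0; q < n_pops; ++q) {
        if (q == p) continue;
        out[pos++] = ci_n[p] ? ci[p * n_pops + q] / ci_n[p] : 0.0;
      }
    return out;
  }

  // variant 1: model-check statistics
  std::vector<double> na_mean(n_pops, 0.0), szvar(n_pops, 0.0);
  std::vector<int> na_n(n_pops, 0), szvar_n(n_pops, 0);
  int n_pairs = n_pops * (n_pops - 1) / 2;
  std::vector<double> das(n_pairs, 0.0), dmu2(n_pairs, 0.0);
  std::vector<int> das_n(n_pairs, 0), dmu2_n(n_pairs, 0);

  for (int l = 0; l < n_loci; ++l) {
    int c1 = 2 * l, c2 = 2 * l + 1;
    std::vector<double> mean_sz(n_pops, 0.0), m2(n_pops, 0.0);
    std::vector<double> ncop(n_pops, 0.0);
    std::vector<std::unordered_map<int, int> > present(n_pops);
    for (int i = 0; i < n_ind; ++i) {
      int a = alleles(i, c1), b = alleles(i, c2);
      if (a <= 0) continue;
      int p = pop[i];
      present[p][a] += 1;
      present[p][b] += 1;
      for (int rep = 0; rep < 2; ++rep) {
        double y = rep == 0 ? (double)a : (double)b;
        ncop[p] += 1.0;
        double d = y - mean_sz[p];
        mean_sz[p] += d / ncop[p];
        m2[p] += d * (y - mean_sz[p]);
      }
    }
    for (int p = 0; p < n_pops; ++p) {
      if (ncop[p] >= 2) {
        na_mean[p] += (double)present[p].size();
        na_n[p] += 1;
        szvar[p] += m2[p] / (ncop[p] - 1.0);
        szvar_n[p] += 1;
      }
    }
    int pr = 0;
    for (int p = 0; p < n_pops - 1; ++p) {
      for (int q = p + 1; q < n_pops; ++q, ++pr) {
        if (ncop[p] >= 2 && ncop[q] >= 2) {
          double d = mean_sz[p] - mean_sz[q];
          dmu2[pr] += d * d;
          dmu2_n[pr] += 1;
          // shared-allele proportion averaged over cross-pop pairs
          double acc = 0.0;
          long cntp = 0;
          for (int i = 0; i < n_ind; ++i) {
            if (pop[i] != p || alleles(i, c1) <= 0) continue;
            int a1 = alleles(i, c1), a2 = alleles(i, c2);
            for (int j = 0; j < n_ind; ++j) {
              if (pop[j] != q || alleles(j, c1) <= 0) continue;
              int b1 = alleles(j, c1), b2 = alleles(j, c2);
              int shared;
              if (a1 == a2) {
                shared = (b1 == a1) + (b2 == a1);
              } else if (b1 == b2) {
                shared = (a1 == b1) + (a2 == b1);
              } else {
                shared = ((a1 == b1) || (a1 == b2)) + ((a2 == b1) || (a2 == b2));
              }
              acc += 0.5 * (double)shared;
              ++cntp;
            }
          }
          if (cntp > 0) {
            das[pr] += 1.0 - acc / (double)cntp;
            das_n[pr] += 1;
          }
        }
      }
    }
  }
  NumericVector out(2 * n_pops + 2 * n_pairs);
  int pos = 0;
  for (int p = 0; p < n_pops; ++p)
    out[pos++] = na_n[p] ? na_mean[p] / na_n[p] : 0.0;
  for (int p = 0; p < n_pops; ++p)
    out[pos++] = szvar_n[p] ? szvar[p] / szvar_n[p] : 0.0;
  for (int pr = 0; pr < n_pairs; ++pr)
    out[pos++] = das_n[pr] ? das[pr] / das_n[pr] : 0.0;
  for (int pr = 0; pr < n_pairs; ++pr)
    out[pos++] = dmu2_n[pr] ? dmu2[pr] / dmu2_n[pr] : 0.0;
  return out;
}
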