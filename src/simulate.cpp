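#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulator under a population-tree demography.
// Time is scaled in units of 2 * n_ref generations; a specific pair of
// lineages in a branch of scaled size lambda coalesces at rate 1/lambda.
// Unlinked sites: one independent genealogy per site, mutations dropped
// as Poisson(theta * total_length) with a single (first) mutation kept,
// mirroring the biallelic infinite-sites view of one site.
//
// modes: 0 histogram, 1 per-site patterns, 2 per-site carrier leaf sets,
//        3 oracle branch lengths for tracked patterns, 4 one genealogy.

struct Event { double time; int type; int arg; }; // type 0 entry(pop), 1 join(idx)

// [[Rcpp::export]]
List cpp_simulate(IntegerVector n, NumericVector age, NumericVector lambda0,
                  NumericMatrix joins, int n_sites, double theta, int mode,
                  int max_m, IntegerVector tracked_keys) {
  const int K = n.size();
  int ntot = 0;
  std::vector<int> offs(K, 0);
  for (int k = 0; k < K; ++k) { offs[k] = ntot; ntot += n[k]; }
  if (ntot < 2) stop("need at least two haploid samples in total");

  // event schedule: sample entries (age > 0) then joins, sorted by time
  std::vector<Event> ev;
  for (int k = 0; k < K; ++k)
    if (age[k] > 0 && n[k] > 0) ev.push_back({age[k], 0, k});
  for (int j = 0; j < joins.nrow(); ++j)
    ev.push_back({joins(j, 0), 1, j});
  std::stable_sort(ev.begin(), ev.end(),
                   [](const Event& a, const Event& b) {
                     if (a.time != b.time) return a.time < b.time;
                     return a.type < b.type;
                   });

  const int maxlin = 2 * ntot + 2;
  std::vector<int> desc((size_t)maxlin * K);
  std::vector<double> birth(maxlin);
  std::vector<int> posInPop(maxlin), popOf(maxlin);
  std::vector<std::vector<int>> leaf; // mode 2/4 only
  const bool want_leaves = (mode == 2 || mode == 4);
  if (want_leaves) leaf.resize(maxlin);

  std::vector<std::vector<int>> members(K);
  for (int k = 0; k < K; ++k) members[k].reserve(ntot);

  // recorded branch segments
  std::vector<int> bdesc((size_t)maxlin * K);
  std::vector<double> blen(maxlin);
  std::vector<int> blin(maxlin);

  // mode 0 accumulators
  std::unordered_map<long long, double> hist;
  double mono = 0, over = 0;
  const long long base = max_m + 1;

  // mode 1/2 outputs
  std::vector<int> site_pos;
  std::vector<int> site_desc;
  List site_leaves_out;
  std::vector<std::vector<int>> site_leaves;

  // mode 3 accumulators
  std::unordered_map<long long, int> tracked;
  for (int i = 0; i < tracked_keys.size(); ++i)
    tracked[(long long)tracked_keys[i]] = i;
  const int ntr = tracked.size();
  std::vector<double> repL(ntr), sumL(ntr, 0.0), sumL2(ntr, 0.0);
  std::vector<int> touched; touched.reserve(ntr);
  double totL_sum = 0.0, totL_sum2 = 0.0;

  std::vector<double> lam(K);
  List genealogy_out;

  const int nrep = (mode == 4) ? 1 : n_sites;
  for (int rep = 0; rep < nrep; ++rep) {
    // reset
    for (int k = 0; k < K; ++k) { members[k].clear(); lam[k] = lambda0[k]; }
    int nlin = 0, nbr = 0, active = 0;
    size_t evptr = 0;
    double t = 0.0;

    auto add_tip = [&](int k, double when) {
      for (int i = 0; i < n[k]; ++i) {
        int id = nlin++;
        for (int kk = 0; kk < K; ++kk) desc[(size_t)id * K + kk] = 0;
        desc[(size_t)id * K + k] = 1;
        birth[id] = when;
        popOf[id] = k;
        posInPop[id] = members[k].size();
        members[k].push_back(id);
        if (want_leaves) leaf[id] = {offs[k] + i};
        ++active;
      }
    };
    for (int k = 0; k < K; ++k)
      if (age[k] <= 0 && n[k] > 0) add_tip(k, 0.0);

    // per-population pair-coalescence rates, maintained incrementally
    std::vector<double> prate(K, 0.0);
    double totrate = 0.0;
    auto refresh_rate = [&](int k) {
      double c = (double)members[k].size();
      double r = c * (c - 1.0) / (2.0 * lam[k]);
      totrate += r - prate[k];
      prate[k] = r;
    };
    for (int k = 0; k < K; ++k) refresh_rate(k);
    int drift = 0;

    while (active > 1 || evptr < ev.size()) {
      if (++drift >= 64) { // guard against float drift in totrate
        drift = 0;
        totrate = 0.0;
        for (int k = 0; k < K; ++k) {
          double c = (double)members[k].size();
          prate[k] = c * (c - 1.0) / (2.0 * lam[k]);
          totrate += prate[k];
        }
      }
      double tnext = (evptr < ev.size()) ? ev[evptr].time : R_PosInf;
      double dt = (totrate > 0) ? R::exp_rand() / totrate : R_PosInf;
      if (t + dt >= tnext) {
        if (!R_finite(tnext))
          stop("lineages can never fully coalesce under this model");
        t = tnext;
        const Event& e = ev[evptr++];
        if (e.type == 0) {
          add_tip(e.arg, t);
          refresh_rate(e.arg);
        } else {
          int into = (int)joins(e.arg, 1), from = (int)joins(e.arg, 2);
          for (int id : members[from]) {
            popOf[id] = into;
            posInPop[id] = members[into].size();
            members[into].push_back(id);
          }
          members[from].clear();
          double la = joins(e.arg, 3);
          if (R_finite(la)) lam[into] = la;
          refresh_rate(into);
          refresh_rate(from);
        }
        continue;
      }
      t += dt;
      // choose population proportional to its pair rate
      double u = R::unif_rand() * totrate, cum = 0.0;
      int k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += prate[kk];
        if (u <= cum) { k = kk; break; }
      }
      int c = members[k].size();
      int r1 = (int)(R::unif_rand() * c); if (r1 >= c) r1 = c - 1;
      int r2 = (int)(R::unif_rand() * (c - 1)); if (r2 >= c - 1) r2 = c - 2;
      if (r2 >= r1) ++r2;
      int i1 = members[k][r1], i2 = members[k][r2];
      // record both child segments
      for (int ch : {i1, i2}) {
        for (int kk = 0; kk < K; ++kk)
          bdesc[(size_t)nbr * K + kk] = desc[(size_t)ch * K + kk];
        blen[nbr] = t - birth[ch];
        blin[nbr] = ch;
        ++nbr;
      }
      int id = nlin++;
      for (int kk = 0; kk < K; ++kk)
        desc[(size_t)id * K + kk] =
          desc[(size_t)i1 * K + kk] + desc[(size_t)i2 * K + kk];
      birth[id] = t;
      popOf[id] = k;
      if (want_leaves) {
        leaf[id].clear();
        leaf[id].insert(leaf[id].end(), leaf[i1].begin(), leaf[i1].end());
        leaf[id].insert(leaf[id].end(), leaf[i2].begin(), leaf[i2].end());
      }
      // i1's slot -> new lineage; swap-remove i2
      members[k][r1] = id;
      posInPop[id] = r1;
      int last = members[k].back();
      members[k][r2] = last;
      posInPop[last] = r2;
      members[k].pop_back();
      --active;
      refresh_rate(k);
    }

    double L = 0.0;
    for (int b = 0; b < nbr; ++b) L += blen[b];

    if (mode == 4) {
      IntegerMatrix dm(nbr, K);
      NumericVector lv(nbr), bt(nbr);
      List lf(nbr);
      for (int b = 0; b < nbr; ++b) {
        for (int kk = 0; kk < K; ++kk) dm(b, kk) = bdesc[(size_t)b * K + kk];
        lv[b] = blen[b];
        bt[b] = birth[blin[b]];
        if (want_leaves) {
          std::vector<int> s = leaf[blin[b]];
          std::sort(s.begin(), s.end());
          lf[b] = IntegerVector(s.begin(), s.end());
        }
      }
      genealogy_out = List::create(_["desc"] = dm, _["length"] = lv,
                                   _["birth"] = bt, _["leaves"] = lf,
                                   _["total_length"] = L, _["tmrca"] = t);
      break;
    }

    if (mode == 3) {
      touched.clear();
      for (int b = 0; b < nbr; ++b) {
        int tot = 0;
        for (int kk = 0; kk < K; ++kk) tot += bdesc[(size_t)b * K + kk];
        if (tot > max_m) continue;
        long long key = 0, mul = 1;
        for (int kk = 0; kk < K; ++kk) {
          key += (long long)bdesc[(size_t)b * K + kk] * mul;
          mul *= base;
        }
        auto it = tracked.find(key);
        if (it == tracked.end()) continue;
        if (repL[it->second] == 0.0) touched.push_back(it->second);
        repL[it->second] += blen[b];
      }
      for (int idx : touched) {
        sumL[idx] += repL[idx];
        sumL2[idx] += repL[idx] * repL[idx];
        repL[idx] = 0.0;
      }
      totL_sum += L; totL_sum2 += L * L;
      continue;
    }

    // modes 0/1/2: drop mutations
    int nmut = (int)R::rpois(theta * L);
    if (nmut == 0) { if (mode == 0) mono += 1; continue; }
    double u = R::unif_rand() * L, cum = 0.0;
    int b = nbr - 1;
    for (int bb = 0; bb < nbr; ++bb) {
      cum += blen[bb];
      if (u <= cum) { b = bb; break; }
    }
    int tot = 0;
    for (int kk = 0; kk < K; ++kk) tot += bdesc[(size_t)b * K + kk];
    if (mode == 0) {
      if (tot > max_m) { over += 1; continue; }
      long long key = 0, mul = 1;
      for (int kk = 0; kk < K; ++kk) {
        key += (long long)bdesc[(size_t)b * K + kk] * mul;
        mul *= base;
      }
      hist[key] += 1;
    } else {
      site_pos.push_back(rep + 1);
      for (int kk = 0; kk < K; ++kk)
        site_desc.push_back(bdesc[(size_t)b * K + kk]);
      if (mode == 2) {
        std::vector<int> s = leaf[blin[b]];
        std::sort(s.begin(), s.end());
        site_leaves.push_back(s);
      }
    }
  }

  if (mode == 4) return genealogy_out;
  if (mode == 3) {
    NumericVector s1(ntr), s2(ntr);
    for (int i = 0; i < ntr; ++i) { s1[i] = sumL[i]; s2[i] = sumL2[i]; }
    return List::create(_["sumL"] = s1, _["sumL2"] = s2,
                        _["total_sumL"] = totL_sum,
                        _["total_sumL2"] = totL_sum2,
                        _["reps"] = n_sites);
  }
  if (mode == 0) {
    int m = hist.size();
    std::vector<long long> keys;
    keys.reserve(m);
    for (auto& kv : hist) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    NumericVector counts(m), keyv(m);
    for (int i = 0; i < m; ++i) { keyv[i] = (double)keys[i]; counts[i] = hist[keys[i]]; }
    return List::create(_["key"] = keyv, _["count"] = counts,
                        _["monomorphic"] = mono, _["overflow"] = over);
  }
  // modes 1/2
  int ns = site_pos.size();
  IntegerMatrix dm(ns, K);
  for (int i = 0; i < ns; ++i)
    for (int kk = 0; kk < K; ++kk) dm(i, kk) = site_desc[(size_t)i * K + kk];
  List lf(ns);
  if (mode == 2)
    for (int i = 0; i < ns; ++i)
      lf[i] = IntegerVector(site_leaves[i].begin(), site_leaves[i].end());
  return List::create(_["pos"] = IntegerVector(site_pos.begin(), site_pos.end()),
                      _["desc"] = dm, _["leaves"] = lf);
}
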