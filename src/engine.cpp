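#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact backward-in-time propagation for rare-allele site patterns.
//
// Within one demographic epoch the ancestral process factorizes across
// branches: branch k holds a_k derived and b_k non-derived lineages,
// and (a_k, b_k) is a small Markov chain with rates (per scaled time,
// pair rate 1/lambda):
//   (a,b) -> (a-1,b)  at C(a,2)/lambda   (derived pair coalescence)
//   (a,b) -> (a,b-1)  at C(b,2)/lambda   (non-derived pair coalescence)
//   (a,b) -> lost     at a*b/lambda      (derived/non-derived: the
//                                         pattern can no longer arise)
// Joins convolve the two branch distributions. The expected time during
// which a single derived lineage subtends exactly the carrier set
// accumulates d acc/dt = sum_k P_k(a=1) prod_{l != k} P_l(a=0) over
// active branches (inactive = frozen ancient branches hold a delta
// distribution and cannot host the singleton).
//
// After the last demographic event a single branch remains and the
// remaining accumulation has the closed form h(a, b):
//   h(0,b) = 0,  h(1,b) = 2 lambda / (b+1),
//   h(a,b) = [1{a=1} + C(a,2) h(a-1,b) + C(b,2) h(a,b-1)] * lambda / R
// with R = C(a,2) + C(b,2) + a b, so no integration to t = infinity is
// ever needed.

struct BranchSys {
  int amax, bmax, nvar, nstate;
  double lambda;
  bool active;
  std::vector<double> dist; // nstate x nvar, state = a*(bmax+1)+b
};

static inline double c2(double x) { return x * (x - 1.0) / 2.0; }

// [[Rcpp::export]]
List cpp_branch_epoch(List branches, IntegerMatrix patvar, NumericVector acc_in,
                      double t0, double t1, double substep, double max_step) {
  const int K = branches.size();
  const int npat = patvar.nrow();
  std::vector<BranchSys> bs(K);
  double Rmax = 0.0;
  for (int k = 0; k < K; ++k) {
    List b = branches[k];
    BranchSys& s = bs[k];
    s.amax = as<int>(b["amax"]);
    s.bmax = as<int>(b["bmax"]);
    s.lambda = as<double>(b["lambda"]);
    s.active = as<bool>(b["active"]);
    NumericMatrix d = b["dist"];
    s.nstate = (s.amax + 1) * (s.bmax + 1);
    s.nvar = d.ncol();
    if (d.nrow() != s.nstate) stop("dist dimension mismatch");
    s.dist.assign(d.begin(), d.end());
    if (s.active) {
      double r = (c2(s.amax) + c2(s.bmax) + (double)s.amax * s.bmax) / s.lambda;
      Rmax = std::max(Rmax, r);
    }
  }
  std::vector<double> acc(acc_in.begin(), acc_in.end());

  double dt = t1 - t0;
  if (dt < 0) stop("t1 < t0");
  int nsub = 1;
  if (dt > 0) {
    nsub = (int)std::ceil(std::max(dt * Rmax / substep, dt / max_step));
    if (nsub < 1) nsub = 1;
  } else nsub = 0;
  double h = (nsub > 0) ? dt / nsub : 0.0;

  // workspaces: per-branch distributions and acc integrated together (RK4)
  std::vector<std::vector<double>> k1(K), k2(K), k3(K), k4(K), tmp(K);
  for (int k = 0; k < K; ++k) {
    size_t n = bs[k].dist.size();
    k1[k].assign(n, 0.0); k2[k].assign(n, 0.0); k3[k].assign(n, 0.0);
    k4[k].assign(n, 0.0); tmp[k].assign(n, 0.0);
  }
  std::vector<size_t> voff(K + 1, 0); // per-branch offsets into p0/p1
  for (int k = 0; k < K; ++k) voff[k + 1] = voff[k] + bs[k].nvar;
  std::vector<double> p0(voff[K]), p1(voff[K]);
  std::vector<double> mv0(K), mv1(K); // per-branch marginals for one variant

  // derivative of one branch's distribution (active branches only)
  auto branch_deriv = [&](const BranchSys& s, const std::vector<double>& d,
                          std::vector<double>& out) {
    const int W = s.bmax + 1;
    for (int v = 0; v < s.nvar; ++v) {
      const double* dv = &d[(size_t)v * s.nstate];
      double* ov = &out[(size_t)v * s.nstate];
      for (int a = 0; a <= s.amax; ++a)
        for (int b = 0; b <= s.bmax; ++b) {
          int i = a * W + b;
          double rate_out = (c2(a) + c2(b) + (double)a * b) / s.lambda;
          double x = -rate_out * dv[i];
          if (a + 1 <= s.amax) x += c2(a + 1) / s.lambda * dv[(a + 1) * W + b];
          if (b + 1 <= s.bmax) x += c2(b + 1) / s.lambda * dv[a * W + b + 1];
          ov[i] = x;
        }
    }
  };

  // acc derivative given current branch distributions
  auto acc_deriv = [&](const std::vector<std::vector<double>>& ds,
                       std::vector<double>& dacc) {
    // per-branch, per-variant a-marginals P(a=0), P(a=1)
    for (int k = 0; k < K; ++k) {
      const BranchSys& s = bs[k];
      const int W = s.bmax + 1;
      for (int v = 0; v < s.nvar; ++v) {
        const double* dv = &ds[k][(size_t)v * s.nstate];
        double q0 = 0.0, q1 = 0.0;
        for (int b = 0; b < W; ++b) q0 += dv[b];
        if (s.amax >= 1) for (int b = 0; b < W; ++b) q1 += dv[W + b];
        p0[voff[k] + v] = q0;
        p1[voff[k] + v] = q1;
      }
    }
    for (int j = 0; j < npat; ++j) {
      for (int k = 0; k < K; ++k) {
        int v = patvar(j, k);
        mv0[k] = p0[voff[k] + v];
        mv1[k] = p1[voff[k] + v];
      }
      double x = 0.0;
      for (int k = 0; k < K; ++k) {
        if (!bs[k].active) continue;
        double prod = mv1[k];
        if (prod == 0.0) continue;
        for (int l = 0; l < K && prod > 0.0; ++l)
          if (l != k) prod *= mv0[l];
        x += prod;
      }
      dacc[j] = x;
    }
  };

  std::vector<double> a1(npat), a2(npat), a3(npat), a4(npat);
  std::vector<std::vector<double>> stage(K);
  for (int k = 0; k < K; ++k) stage[k].assign(bs[k].dist.size(), 0.0);

  for (int s = 0; s < nsub; ++s) {
    // k1
    for (int k = 0; k < K; ++k)
      if (bs[k].active) branch_deriv(bs[k], bs[k].dist, k1[k]);
      else std::fill(k1[k].begin(), k1[k].end(), 0.0);
    for (int k = 0; k < K; ++k) stage[k] = bs[k].dist;
    acc_deriv(stage, a1);
    // k2
    for (int k = 0; k < K; ++k)
      for (size_t i = 0; i < stage[k].size(); ++i)
        stage[k][i] = bs[k].dist[i] + 0.5 * h * k1[k][i];
    for (int k = 0; k < K; ++k)
      if (bs[k].active) branch_deriv(bs[k], stage[k], k2[k]);
      else std::fill(k2[k].begin(), k2[k].end(), 0.0);
    acc_deriv(stage, a2);
    // k3
    for (int k = 0; k < K; ++k)
      for (size_t i = 0; i < stage[k].size(); ++i)
        stage[k][i] = bs[k].dist[i] + 0.5 * h * k2[k][i];
    for (int k = 0; k < K; ++k)
      if (bs[k].active) branch_deriv(bs[k], stage[k], k3[k]);
      else std::fill(k3[k].begin(), k3[k].end(), 0.0);
    acc_deriv(stage, a3);
    // k4
    for (int k = 0; k < K; ++k)
      for (size_t i = 0; i < stage[k].size(); ++i)
        stage[k][i] = bs[k].dist[i] + h * k3[k][i];
    for (int k = 0; k < K; ++k)
      if (bs[k].active) branch_deriv(bs[k], stage[k], k4[k]);
      else std::fill(k4[k].begin(), k4[k].end(), 0.0);
    acc_deriv(stage, a4);

    for (int k = 0; k < K; ++k)
      for (size_t i = 0; i < bs[k].dist.size(); ++i)
        bs[k].dist[i] += h / 6.0 *
          (k1[k][i] + 2.0 * k2[k][i] + 2.0 * k3[k][i] + k4[k][i]);
    for (int j = 0; j < npat; ++j)
      acc[j] += h / 6.0 * (a1[j] + 2.0 * a2[j] + 2.0 * a3[j] + a4[j]);
  }

  List out(K);
  for (int k = 0; k < K; ++k) {
    for (size_t i = 0; i < bs[k].dist.size(); ++i) {
      if (bs[k].dist[i] < 0) {
        if (bs[k].dist[i] < -1e-8)
          stop("negative probability beyond tolerance (numerical failure)");
        bs[k].dist[i] = 0.0;
      }
    }
    NumericMatrix d(bs[k].nstate, bs[k].nvar);
    std::copy(bs[k].dist.begin(), bs[k].dist.end(), d.begin());
    out[k] = d;
  }
  return List::create(_["dist"] = out,
                      _["acc"] = NumericVector(acc.begin(), acc.end()));
}

// Convolve two branch distributions at a join, for the given variant
// pairs (0-based columns of A and B).
// [[Rcpp::export]]
NumericMatrix cpp_convolve_join(NumericMatrix A, int amaxA, int bmaxA,
                                NumericMatrix B, int amaxB, int bmaxB,
                                IntegerMatrix pairs, int amax_out) {
  const int WA = bmaxA + 1, WB = bmaxB + 1;
  const int bmax_out = bmaxA + bmaxB;
  const int W = bmax_out + 1;
  const int nstate = (amax_out + 1) * W;
  const int np = pairs.nrow();
  NumericMatrix out(nstate, np);
  for (int p = 0; p < np; ++p) {
    const double* da = &A(0, pairs(p, 0));
    const double* db = &B(0, pairs(p, 1));
    double* o = &out(0, p);
    for (int a1 = 0; a1 <= amaxA; ++a1)
      for (int b1 = 0; b1 <= bmaxA; ++b1) {
        double x = da[a1 * WA + b1];
        if (x == 0.0) continue;
        for (int a2 = 0; a2 <= amaxB && a1 + a2 <= amax_out; ++a2)
          for (int b2 = 0; b2 <= bmaxB; ++b2) {
            double y = db[a2 * WB + b2];
            if (y != 0.0) o[(a1 + a2) * W + b1 + b2] += x * y;
          }
      }
  }
  return out;
}

// Closed-form expected remaining singleton time h(a, b) for a single
// branch of size lambda. h(a, 0) with a >= 1 is infinite (no
// non-derived lineage left to end the accumulation) and returned as Inf.
// [[Rcpp::export]]
NumericMatrix cpp_h_table(int amax, int bmax, double lambda) {
  NumericMatrix hm(amax + 1, bmax + 1);
  for (int b = 0; b <= bmax; ++b) hm(0, b) = 0.0;
  for (int a = 1; a <= amax; ++a) hm(a, 0) = R_PosInf;
  for (int a = 1; a <= amax; ++a)
    for (int b = 1; b <= bmax; ++b) {
      double R = c2(a) + c2(b) + (double)a * b;
      double num = (a == 1 ? 1.0 : 0.0) * lambda;
      if (a >= 2) num += c2(a) * hm(a - 1, b);       // coeff 0 when a < 2
      if (b >= 2) num += c2(b) * hm(a, b - 1);       // avoids 0 * Inf at b=1
      hm(a, b) = num / R;
    }
  return hm;
}
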