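#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// exp() for x in [-45, 0], relative accuracy ~2e-13; branch-free so the
// log-sum-exp inner loops stay cheap (this is where the kernel spends its
// time).
static inline double fexp(double x) {
  const double L2E = 1.4426950408889634074;
  const double C1 = 0.693147180369123816490;   // ln2 split (hi)
  const double C2 = 1.90821492927058770002e-10; // ln2 split (lo)
  const int ni = (int)(x * L2E - 0.5);  // round-to-nearest for x <= 0
  const double n = (double)ni;
  double r = (x - n * C1) - n * C2;
  double p = 1.0 / 3628800.0;
  p = p * r + 1.0 / 362880.0;
  p = p * r + 1.0 / 40320.0;
  p = p * r + 1.0 / 5040.0;
  p = p * r + 1.0 / 720.0;
  p = p * r + 1.0 / 120.0;
  p = p * r + 1.0 / 24.0;
  p = p * r + 1.0 / 6.0;
  p = p * r + 0.5;
  p = p * r + 1.0;
  p = p * r + 1.0;
  const uint64_t bits = (uint64_t)((int64_t)ni + 1023) << 52;
  double s;
  std::memcpy(&s, &bits, sizeof(s));
  return p * s;
}

// Composite-likelihood kernel for the bivariate four-component mixture of
// marginal GWAS effect estimates.
//
// Each SNP k has a tagging set of size nstar and LD weight s = l_k / nstar.
// The latent composition of the tagging set across the (G1, G2, GC, G0)
// components is enumerated (rows of `comps`, counts for the three non-null
// components); the per-composition bivariate covariance of (tau1_hat,
// tau2_hat) is linear in the counts:
//   var1 = s * (i*A1 + j*A2 + c*AC1) + b1
//   var2 = s * (i*B1 + j*B2 + c*BC2) + b2
//   cov  = s * (i*C1 + j*C2 + c*CC ) + b0
// with the nine coefficients and three bases precomputed in R from the model
// parameters. Composition priors are multinomial, renormalised over the
// enumerated (possibly truncated) set.
//
// SNPs sharing (nstar, s) are grouped by the caller so per-composition
// covariance work is done once per group.
//
// [[Rcpp::export]]
List cl_kernel(NumericVector tau1, NumericVector tau2,
               IntegerVector group,            // 1-based group index per SNP
               IntegerVector g_nstar, NumericVector g_s,
               IntegerMatrix comps,            // J x 3 counts (G1, G2, GC)
               NumericVector pi,               // length 4: pi1, pi2, piC, pi0
               NumericVector coef,             // A1 A2 AC1 B1 B2 BC2 C1 C2 CC
               NumericVector base,             // b1 b2 b0
               bool want_loglik, bool want_counts, bool want_post) {
  const int K = tau1.size();
  const int G = g_nstar.size();
  const int J = comps.nrow();
  const double jitter = 1e-12;
  const double LOG2PI = 1.8378770664093454836;

  // order SNPs by group (counting sort); gstart[g] is the first slot of
  // 0-based group g, gstart[G] == K
  std::vector<int> gcount(G, 0);
  for (int k = 0; k < K; ++k) gcount[group[k] - 1]++;
  std::vector<int> gstart(G + 1, 0);
  for (int g = 0; g < G; ++g) gstart[g + 1] = gstart[g] + gcount[g];
  std::vector<int> snp_of(K);
  {
    std::vector<int> cur(gstart.begin(), gstart.end());
    for (int k = 0; k < K; ++k) snp_of[cur[group[k] - 1]++] = k;
  }

  // lgamma table for integers 0..max(nstar)+1
  int max_n = 0;
  for (int g = 0; g < G; ++g) if (g_nstar[g] > max_n) max_n = g_nstar[g];
  std::vector<double> lgam(max_n + 2);
  for (int i = 0; i <= max_n + 1; ++i) lgam[i] = std::lgamma((double)(i + 1)); // lgam[i] = log(i!)

  double lpi[4];
  for (int h = 0; h < 4; ++h) lpi[h] = pi[h] > 0 ? std::log(pi[h]) : R_NegInf;

  const double A1 = coef[0], A2 = coef[1], AC1 = coef[2];
  const double B1 = coef[3], B2 = coef[4], BC2 = coef[5];
  const double C1 = coef[6], C2 = coef[7], CC = coef[8];
  const double b1 = base[0], b2 = base[1], b0 = base[2];

  NumericVector loglik(want_loglik ? K : 0);
  NumericMatrix post;
  if (want_post) post = NumericMatrix(K, J);

  double cl = 0.0;
  double e1 = 0.0, e2 = 0.0, ec = 0.0, sum_nstar = 0.0;
  long clamp_count = 0;
  bool bad = false; int bad_snp = -1;

  std::vector<double> logw(J), P11(J), P22(J), P12(J);
  std::vector<int> valid(J);
  // compacted per-group arrays (only valid compositions)
  std::vector<double> cw(J), c11(J), c22(J), c12(J), lp(J);
  std::vector<int> cjid(J);

  for (int g = 0; g < G; ++g) {
    if (gstart[g + 1] == gstart[g]) continue;  // group with no SNPs
    const int ns = g_nstar[g];
    const double s = g_s[g];
    // composition priors, renormalised over the enumerated set
    int nvalid = 0;
    double zmax = R_NegInf;
    for (int j = 0; j < J; ++j) {
      const int ci = comps(j, 0), cj = comps(j, 1), cc = comps(j, 2);
      const int c0 = ns - ci - cj - cc;
      valid[j] = 0;
      if (c0 < 0) continue;
      double lpr = lgam[ns] - lgam[ci] - lgam[cj] - lgam[cc] - lgam[c0];
      lpr += (ci > 0 ? ci * lpi[0] : 0.0) + (cj > 0 ? cj * lpi[1] : 0.0) +
             (cc > 0 ? cc * lpi[2] : 0.0) + (c0 > 0 ? c0 * lpi[3] : 0.0);
      if (!R_finite(lpr)) continue;
      valid[j] = 1;
      logw[j] = lpr;
      if (lpr > zmax) zmax = lpr;
      ++nvalid;
    }
    if (nvalid == 0) { bad = true; bad_snp = snp_of[gstart[g]]; break; }
    double zsum = 0.0;
    for (int j = 0; j < J; ++j) if (valid[j]) zsum += std::exp(logw[j] - zmax);
    const double lZ = zmax + std::log(zsum);

    for (int j = 0; j < J; ++j) {
      if (!valid[j]) continue;
      const double ci = comps(j, 0), cj = comps(j, 1), cc = comps(j, 2);
      double v1 = s * (ci * A1 + cj * A2 + cc * AC1) + b1 + jitter;
      double v2 = s * (ci * B1 + cj * B2 + cc * BC2) + b2 + jitter;
      double cv = s * (ci * C1 + cj * C2 + cc * CC) + b0;
      const double lim = 0.999 * std::sqrt(v1 * v2);
      if (std::fabs(cv) >= lim) { cv = (cv > 0 ? lim : -lim); ++clamp_count; }
      const double det = v1 * v2 - cv * cv;
      logw[j] += -lZ - LOG2PI - 0.5 * std::log(det);
      P11[j] = v2 / det;
      P22[j] = v1 / det;
      P12[j] = -cv / det;
    }

    int nv = 0;
    for (int j = 0; j < J; ++j) {
      if (!valid[j]) continue;
      cjid[nv] = j; ++nv;
    }
    // order by the per-composition density bound logw (quad form >= 0, so
    // lp_j <= logw_j); lets the SNP loop stop exactly where contributions
    // fall below the log-sum-exp floor
    std::sort(cjid.begin(), cjid.begin() + nv,
              [&](int a, int b) { return logw[a] > logw[b]; });
    for (int j = 0; j < nv; ++j) {
      const int jj = cjid[j];
      cw[j] = logw[jj]; c11[j] = 0.5 * P11[jj]; c22[j] = 0.5 * P22[jj];
      c12[j] = P12[jj];
    }

    const double *RESTRICT pw = cw.data();
    const double *RESTRICT p11 = c11.data();
    const double *RESTRICT p12c = c12.data();
    const double *RESTRICT p22 = c22.data();
    double *RESTRICT plp = lp.data();
    const bool small_nv = nv <= 48;

    for (int idx = gstart[g]; idx < gstart[g + 1]; ++idx) {
      const int k = snp_of[idx];
      const double t1 = tau1[k], t2 = tau2[k];
      const double q1 = t1 * t1, q12 = t1 * t2, q2 = t2 * t2;
      double m = R_NegInf;
      int nstop = nv;
      double sum = 0.0;
      if (small_nv) {
        // branch-free path (vectorizes); terms below the floor are clamped,
        // adding at most nv * exp(-45) relative error
        for (int j = 0; j < nv; ++j)
          plp[j] = pw[j] - (p11[j] * q1 + p12c[j] * q12 + p22[j] * q2);
        for (int j = 0; j < nv; ++j) m = plp[j] > m ? plp[j] : m;
        if (!R_finite(m)) { bad = true; bad_snp = k; break; }
        for (int j = 0; j < nv; ++j) {
          double d = plp[j] - m;
          sum += fexp(d < -45.0 ? -45.0 : d);
        }
      } else {
        // the density bound cw is sorted: stop exactly where contributions
        // fall below the log-sum-exp floor
        for (int j = 0; j < nv; ++j) {
          if (pw[j] < m - 45.0) { nstop = j; break; }
          const double v = pw[j] - (p11[j] * q1 + p12c[j] * q12 + p22[j] * q2);
          plp[j] = v;
          if (v > m) m = v;
        }
        if (!R_finite(m)) { bad = true; bad_snp = k; break; }
        for (int j = 0; j < nstop; ++j) {
          const double d = plp[j] - m;
          if (d > -45.0) sum += fexp(d);
        }
      }
      const double ll = m + std::log(sum);
      cl += ll;
      if (want_loglik) loglik[k] = ll;
      if (want_counts || want_post) {
        for (int j = 0; j < nstop; ++j) {
          const double d = lp[j] - ll;
          if (d > -45.0) {
            const double p = fexp(d);
            if (want_post) post(k, cjid[j]) = p;
            e1 += p * comps(cjid[j], 0);
            e2 += p * comps(cjid[j], 1);
            ec += p * comps(cjid[j], 2);
          }
        }
        sum_nstar += ns;
      }
    }
    if (bad) break;
  }

  List out = List::create(
    _["cl"] = cl,
    _["clamp_count"] = (double)clamp_count,
    _["bad"] = bad,
    _["bad_snp"] = bad_snp + 1);
  if (want_loglik) out["loglik"] = loglik;
  if (want_counts) out["exp_counts"] = NumericVector::create(e1, e2, ec, sum_nstar);
  if (want_post) out["post"] = post;
  return out;
}
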