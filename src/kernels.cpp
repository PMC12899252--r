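// Hot per-iteration kernels for the phasing engine. These mirror the R
// reference implementations (pb_core, pa_core, the step combinators) and are
// cross-checked against them in the test suite.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

// monotone map from double to uint64 (total order, NaN-free input assumed)
static inline uint64_t dkey(double x) {
  uint64_t u;
  std::memcpy(&u, &x, 8);
  return (u & 0x8000000000000000ULL) ? ~u : (u | 0x8000000000000000ULL);
}

// stable LSD radix sort of (key, payload) pairs by key
static void radix_sort_pairs(std::vector<std::pair<uint64_t, int> > &a,
                             std::vector<std::pair<uint64_t, int> > &tmp) {
  const size_t n = a.size();
  size_t cnt[256];
  for (int pass = 0; pass < 8; pass++) {
    const int sh = pass * 8;
    std::memset(cnt, 0, sizeof(cnt));
    for (size_t i = 0; i < n; i++) cnt[(a[i].first >> sh) & 0xFF]++;
    size_t pos = 0;
    size_t start[256];
    for (int b = 0; b < 256; b++) { start[b] = pos; pos += cnt[b]; }
    for (size_t i = 0; i < n; i++) tmp[start[(a[i].first >> sh) & 0xFF]++] = a[i];
    a.swap(tmp);
  }
}

// Fourier amplitude projection, in place, plus R-factor bookkeeping.
// F: complex fft coefficients of the current map (modified in place).
// coef/refl: orbit expansion (1-based linear indices / owning reflection).
// rep_of: representative coefficient per reflection. weights: length 0 = all 1.
// Returns c(r_work, r_free, lambda_w, kappa); r_free is NA without free set.
// [[Rcpp::export]]
NumericVector pb_kernel(ComplexVector F, IntegerVector coef, IntegerVector refl,
                        IntegerVector rep_of, LogicalVector work,
                        LogicalVector free_set, NumericVector f_obs,
                        NumericVector weights) {
  const int nr = rep_of.size();
  const bool has_w = weights.size() == nr;
  std::vector<double> amp(nr);
  double sum_fc_work = 0, sum_fo_work = 0, sum_wfo_work = 0, sum_fo_free = 0;
  for (int i = 0; i < nr; i++) {
    const Rcomplex z = F[rep_of[i] - 1];
    amp[i] = std::sqrt(z.r * z.r + z.i * z.i);
    if (work[i]) {
      sum_fc_work += amp[i];
      sum_fo_work += f_obs[i];
      sum_wfo_work += (has_w ? weights[i] : 1.0) * f_obs[i];
    } else if (free_set[i]) {
      sum_fo_free += f_obs[i];
    }
  }
  if (sum_fc_work <= 0)
    stop("degenerate input: all calculated work amplitudes are zero");
  const double lam_m = sum_fo_work / sum_fc_work;  // metrics scale (unweighted)
  const double lam_w = sum_wfo_work / sum_fc_work; // PB scale
  const double kappa = lam_m;                      // fill ratio, Eq of the fills
  double rw_num = 0, rf_num = 0;
  bool any_free = false;
  std::vector<double> target(nr);
  for (int i = 0; i < nr; i++) {
    const double w = has_w ? weights[i] : 1.0;
    if (work[i]) {
      target[i] = w * f_obs[i] / lam_w;
      rw_num += std::fabs(f_obs[i] - lam_m * amp[i]);
    } else {
      // filled reflections keep the calculated amplitude on the map scale
      // (the fill ratio matters only when reporting on the observed scale);
      // any weighted ratio here feeds back on itself and diverges
      target[i] = amp[i];
      if (free_set[i]) {
        any_free = true;
        rf_num += std::fabs(f_obs[i] - lam_m * amp[i]);
      }
    }
  }
  const int nc = coef.size();
  for (int j = 0; j < nc; j++) {
    const int ci = coef[j] - 1;
    const Rcomplex z = F[ci];
    const double a = std::sqrt(z.r * z.r + z.i * z.i);
    const double t = target[refl[j] - 1];
    if (a > 0) {
      const double sc = t / a;
      F[ci].r = z.r * sc;
      F[ci].i = z.i * sc;
    } else {
      F[ci].r = t;
      F[ci].i = 0;
    }
  }
  return NumericVector::create(rw_num / sum_fo_work,
                               any_free ? rf_num / sum_fo_free : NA_REAL,
                               lam_w, kappa);
}

// Real-space projection: zero outside pidx, rank-order remap inside
// (stable sort = ties broken by voxel index; pidx must be ascending).
// [[Rcpp::export]]
NumericVector pa_kernel(NumericVector x, IntegerVector pidx,
                        NumericVector targets) {
  const int N = x.size(), m = pidx.size();
  NumericVector out(N);  // zero-filled
  const double *xp = x.begin();
  const int *pp = pidx.begin();
  // radix sort keyed on value; stability + ascending pidx = ties broken by
  // voxel index
  std::vector<std::pair<uint64_t, int> > kv(m), tmp(m);
  for (int i = 0; i < m; i++) kv[i] = std::make_pair(dkey(xp[pp[i] - 1]), pp[i] - 1);
  radix_sort_pairs(kv, tmp);
  for (int r = 0; r < m; r++) out[kv[r].second] = targets[r];
  return out;
}

// One partitioned update + regional density deviations in a single pass.
// alg: 1 = f1/f2 (term 2*PAPB - PA - PB), 2 = f3/f4 (PAPB - PA),
//      3 = f5/f6 (PAPB - PB), 4 = HIO (protein <- PAPB, term PAPB - rho).
// pa may have length 0 when the formula does not need it.
// [[Rcpp::export]]
List combine_kernel(NumericVector rho, NumericVector pbr, NumericVector papb,
                    NumericVector pa, IntegerVector pidx, int alg,
                    double beta_eff, double gamma_eff) {
  const int N = rho.size(), m = pidx.size();
  NumericVector out(N);
  double abs_pbr_all = 0;
  for (int i = 0; i < N; i++) {
    out[i] = rho[i] - gamma_eff * pbr[i];
    abs_pbr_all += std::fabs(pbr[i]);
  }
  double abs_pbr_prot = 0, dev_sum = 0;
  for (int k = 0; k < m; k++) {
    const int i = pidx[k] - 1;
    abs_pbr_prot += std::fabs(pbr[i]);
    double term;
    switch (alg) {
      case 1: term = 2 * papb[i] - pa[i] - pbr[i]; break;
      case 2: term = papb[i] - pa[i]; break;
      case 3: term = papb[i] - pbr[i]; break;
      default: term = papb[i] - rho[i]; break;
    }
    dev_sum += std::fabs(term);
    out[i] = (alg == 4) ? papb[i] : papb[i] + beta_eff * term;
  }
  const double dev_s = N > m ? (abs_pbr_all - abs_pbr_prot) / (N - m) : 0.0;
  return List::create(_["out"] = out, _["dev_p"] = dev_sum / m,
                      _["dev_s"] = dev_s);
}
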