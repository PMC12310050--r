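// Scaled forward-backward kernel for the Wright-Fisher HMM.
//
// The single-generation transition matrix is effectively banded: the
// per-generation drift standard deviation is small relative to the node
// spacing (by design of the Chebychev grid), so each row has nonzero mass
// in a narrow window of destination states.  The kernel detects the
// nonzero band of each row/column once and restricts all products to it.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".fb_core")]]
List fb_core(const NumericMatrix& P, const NumericVector& init,
             const IntegerVector& obs_t, const NumericMatrix& emit,
             const int TT, const NumericVector& g, const bool want_gamma) {
  const int M = P.nrow();
  const double band_tol = 1e-15;

  // row bands (for backward gather) and column bands (forward gather)
  std::vector<int> rlo(M), rhi(M), clo(M), chi(M);
  for (int i = 0; i < M; ++i) {
    int lo = 0, hi = M - 1;
    while (lo < M - 1 && P(i, lo) <= band_tol) ++lo;
    while (hi > 0 && P(i, hi) <= band_tol) --hi;
    if (lo > hi) { lo = hi = i; }
    rlo[i] = lo; rhi[i] = hi;
  }
  for (int j = 0; j < M; ++j) {
    int lo = 0, hi = M - 1;
    while (lo < M - 1 && P(lo, j) <= band_tol) ++lo;
    while (hi > 0 && P(hi, j) <= band_tol) --hi;
    if (lo > hi) { lo = hi = j; }
    clo[j] = lo; chi[j] = hi;
  }

  // map generation (1-based) -> emission row, or -1
  std::vector<int> erow(TT + 1, -1);
  for (int k = 0; k < obs_t.size(); ++k) erow[obs_t[k]] = k;

  // forward variables stored M x TT so each generation is contiguous
  NumericMatrix A(M, TT);
  NumericVector cs(TT);
  std::vector<double> v(M), w(M);
  const double* pP = P.begin();

  double c0 = 0.0;
  for (int j = 0; j < M; ++j) {
    double x = init[j];
    if (erow[1] >= 0) x *= emit(erow[1], j);
    v[j] = x; c0 += x;
  }
  if (!(c0 > 0.0)) return List::create(_["ll"] = R_NegInf);
  cs[0] = c0;
  for (int j = 0; j < M; ++j) A(j, 0) = v[j] / c0;

  for (int t = 1; t < TT; ++t) {
    double ct = 0.0;
    const int ek = erow[t + 1];
    const double* prev = &A(0, t - 1);
    for (int j = 0; j < M; ++j) {
      double acc = 0.0;
      const double* col = pP + (size_t)j * M;
      for (int i = clo[j]; i <= chi[j]; ++i) acc += prev[i] * col[i];
      if (ek >= 0) acc *= emit(ek, j);
      v[j] = acc; ct += acc;
    }
    if (!(ct > 0.0)) return List::create(_["ll"] = R_NegInf);
    cs[t] = ct;
    for (int j = 0; j < M; ++j) A(j, t) = v[j] / ct;
  }
  double ll = 0.0;
  for (int t = 0; t < TT; ++t) ll += std::log(cs[t]);

  // backward pass with on-the-fly accumulators; P is transposed first so
  // the row-band gathers below read contiguous memory
  std::vector<double> Pt((size_t)M * M);
  for (int j = 0; j < M; ++j)
    for (int i = 0; i < M; ++i)
      Pt[(size_t)i * M + j] = pP[(size_t)j * M + i];
  std::vector<double> bhat(M, 1.0), gsum(M, 0.0), gamma_t(M);
  NumericVector gamma1(M), gammaT(M);
  NumericMatrix gamma_full = want_gamma ? NumericMatrix(TT, M)
                                        : NumericMatrix(0, 0);
  for (int j = 0; j < M; ++j) gammaT[j] = A(j, TT - 1);
  if (want_gamma)
    for (int j = 0; j < M; ++j) gamma_full(TT - 1, j) = gammaT[j];

  double S1 = 0.0;
  if (TT == 1) {
    for (int j = 0; j < M; ++j) gamma1[j] = gammaT[j];
  }
  for (int t = TT - 2; t >= 0; --t) {
    const int ek = erow[t + 2];
    for (int j = 0; j < M; ++j) {
      double x = bhat[j];
      if (ek >= 0) x *= emit(ek, j);
      w[j] = x;
    }
    const double ci = 1.0 / cs[t + 1];
    const double* at = &A(0, t);
    for (int i = 0; i < M; ++i) {
      double u1 = 0.0, u2 = 0.0;
      const double* prow = &Pt[(size_t)i * M];
      for (int j = rlo[i]; j <= rhi[i]; ++j) {
        const double pw = prow[j] * w[j];
        u1 += pw;
        u2 += pw * g[j];
      }
      const double bt = u1 * ci;
      const double gm = at[i] * bt;
      gamma_t[i] = gm;
      gsum[i] += gm;
      S1 += at[i] * g[i] * u2 * ci - gm * g[i] * g[i];
      bhat[i] = bt;
    }
    if (want_gamma)
      for (int j = 0; j < M; ++j) gamma_full(t, j) = gamma_t[j];
  }
  if (TT > 1)
    for (int j = 0; j < M; ++j) gamma1[j] = gamma_t[j];

  double Ac = 0.0, Bc = 0.0, Cc = 0.0, S0 = 0.0;
  for (int j = 0; j < M; ++j) {
    const double h = g[j] * (1.0 - g[j]);
    Ac += gsum[j] * h;
    Bc += gsum[j] * g[j] * h;
    Cc += gsum[j] * g[j] * g[j] * h;
    S0 += (gammaT[j] - gamma1[j]) * g[j];
  }

  List out = List::create(
    _["ll"] = ll, _["gamma1"] = gamma1, _["gammaT"] = gammaT,
    _["acc"] = List::create(_["A"] = Ac, _["B"] = Bc, _["C"] = Cc,
                            _["S0"] = S0, _["S1"] = S1));
  if (want_gamma) out["gamma"] = gamma_full;
  return out;
}

// Banded fill of the transition matrix: for each interior row only the
// cuts within ~40 standard deviations of the mean have CDF values away
// from 0/1, so the normal CDF is evaluated only there.
// [[Rcpp::export(name = ".transition_core")]]
NumericMatrix transition_core(const NumericVector& cuts,
                              const NumericVector& mu,
                              const NumericVector& sd,
                              const IntegerVector& interior, const int M) {
  NumericMatrix P(M, M);
  const int nc = cuts.size();             // M + 1
  for (int r = 0; r < interior.size(); ++r) {
    const int i = interior[r] - 1;        // 1-based from R
    const double m = mu[r], s = sd[r];
    const double lo = m - 40.0 * s, hi = m + 40.0 * s;
    // first cut index with cuts[j] > lo (cuts[0] = -Inf)
    int jlo = std::upper_bound(cuts.begin(), cuts.end(), lo) - cuts.begin();
    int jhi = std::lower_bound(cuts.begin(), cuts.end(), hi) - cuts.begin();
    if (jlo < 1) jlo = 1;
    if (jhi > nc - 1) jhi = nc - 1;
    if (jlo > jhi) {                      // mean beyond the last finite cut
      int j = (m <= cuts[1]) ? 0 : M - 1;
      if (jlo <= nc - 1 && cuts[jlo - 1] < m && m < cuts[jlo]) j = jlo - 1;
      P(i, j) = 1.0;
      continue;
    }
    double prev = 0.0;                    // CDF at cuts[jlo - 1] (tail ~ 0)
    for (int j = jlo; j <= jhi; ++j) {
      const double c = R::pnorm(cuts[j], m, s, 1, 0);
      P(i, j - 1) = c - prev;
      prev = c;
    }
    if (jhi < nc - 1)                     // remaining upper-tail mass
      P(i, jhi) = 1.0 - prev;
  }
  return P;
}

// P^k for a banded transition matrix, computed row by row: propagate a
// unit vector k times through P, tracking the growing support window.
// [[Rcpp::export(name = ".band_mat_pow")]]
NumericMatrix band_mat_pow(const NumericMatrix& P, const int k) {
  const int M = P.nrow();
  const double band_tol = 1e-15;
  std::vector<int> rlo(M), rhi(M);
  for (int i = 0; i < M; ++i) {
    int lo = 0, hi = M - 1;
    while (lo < M - 1 && P(i, lo) <= band_tol) ++lo;
    while (hi > 0 && P(i, hi) <= band_tol) --hi;
    if (lo > hi) { lo = hi = i; }
    rlo[i] = lo; rhi[i] = hi;
  }
  const double* pP = P.begin();
  NumericMatrix R(M, M);
  std::vector<double> v(M), w(M);
  for (int r = 0; r < M; ++r) {
    std::fill(v.begin(), v.end(), 0.0);
    v[r] = 1.0;
    int lo = r, hi = r;
    for (int step = 0; step < k; ++step) {
      int nlo = M - 1, nhi = 0;
      for (int i = lo; i <= hi; ++i) {
        if (v[i] == 0.0) continue;
        if (rlo[i] < nlo) nlo = rlo[i];
        if (rhi[i] > nhi) nhi = rhi[i];
      }
      if (nlo > nhi) { nlo = lo; nhi = hi; }
      std::fill(w.begin() + nlo, w.begin() + nhi + 1, 0.0);
      for (int i = lo; i <= hi; ++i) {
        const double vi = v[i];
        if (vi == 0.0) continue;
        for (int j = rlo[i]; j <= rhi[i]; ++j)
          w[j] += vi * pP[(size_t)j * M + i];
      }
      for (int j = nlo; j <= nhi; ++j) v[j] = w[j];
      for (int j = lo; j < nlo; ++j) v[j] = 0.0;
      for (int j = nhi + 1; j <= hi; ++j) v[j] = 0.0;
      lo = nlo; hi = nhi;
    }
    for (int j = lo; j <= hi; ++j) R(r, j) = v[j];
  }
  return R;
}
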