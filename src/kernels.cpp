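#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pooled trial-log likelihood over the full parameter grid, evaluated by
// table interpolation.
//
// Inputs:
//   lnalpha: [nMAF x nSF] ln(threshold) at each (M, A, F) grid combination
//            (M fastest) for each distinct trial spatial frequency.
//   cell_sf: 1-based column index into lnalpha per pooled trial cell.
//   cell_lnc, n1, n0: ln(contrast) and response counts per cell.
//   T1, T0: [n_z x nkl] tables of log P and log(1-P) on a uniform axis of
//            z0 = ln(c) - ln(alpha), one column per (beta, delta) node
//            (beta fastest).
//   z0min, dz: origin and step of the table axis.
//
// Output: log-likelihood vector of length nMAF * nkl, ordered (MAF, beta,
// delta) to match the R posterior array.
//
// Two stages per spatial frequency: (1) accumulate the pooled cell
// likelihoods on a dense uniform ln(alpha) axis (n_dense points spanning
// that frequency's ln(alpha) range) by linear interpolation into the z0
// tables; (2) map all dense curves onto the grid's ln(alpha) values in a
// single accumulation pass over the output. Interpolation error is bounded
// by the curvature of log P over one step and is validated against the
// exact evaluation in the test suite.
// [[Rcpp::export]]
NumericVector cpp_pooled_loglik(NumericMatrix lnalpha, IntegerVector cell_sf,
                                NumericVector cell_lnc, NumericVector n1,
                                NumericVector n0, NumericMatrix T1,
                                NumericMatrix T0, double z0min, double dz,
                                int nkl, int n_dense) {
  const int nmaf = lnalpha.nrow();
  const int nsf = lnalpha.ncol();
  const int ncell = cell_sf.size();
  const int nz = T1.nrow();
  NumericVector out(static_cast<R_xlen_t>(nmaf) * nkl);

  std::vector<int> active;
  for (int f = 0; f < nsf; ++f) {
    for (int c = 0; c < ncell; ++c) {
      if (cell_sf[c] - 1 == f) { active.push_back(f); break; }
    }
  }
  const int nact = static_cast<int>(active.size());
  if (nact == 0) return out;

  // stage 1: dense pooled log-likelihood curves, one block per active SF
  std::vector<double> G(static_cast<size_t>(nact) * n_dense * nkl, 0.0);
  std::vector<double> amin(nact), da(nact);
  std::vector<double> cw(n_dense);
  std::vector<int> cm(n_dense);
  for (int s = 0; s < nact; ++s) {
    const int f = active[s];
    double lo = R_PosInf, hi = R_NegInf;
    for (int m = 0; m < nmaf; ++m) {
      const double a = lnalpha(m, f);
      if (a < lo) lo = a;
      if (a > hi) hi = a;
    }
    amin[s] = lo;
    da[s] = (hi > lo) ? (hi - lo) / (n_dense - 1) : 1.0;
    double *Gs = &G[static_cast<size_t>(s) * n_dense * nkl];
    for (int c = 0; c < ncell; ++c) {
      if (cell_sf[c] - 1 != f) continue;
      const double lnc = cell_lnc[c];
      const double w1 = n1[c], w0 = n0[c];
      for (int i = 0; i < n_dense; ++i) {
        double x = (lnc - (lo + i * da[s]) - z0min) / dz;
        int m = static_cast<int>(std::floor(x));
        if (m < 0) { m = 0; x = 0.0; }
        else if (m > nz - 2) { m = nz - 2; x = nz - 1; }
        cm[i] = m;
        cw[i] = x - m;
      }
      for (int kl = 0; kl < nkl; ++kl) {
        const double *t1 = &T1(0, kl);
        const double *t0 = &T0(0, kl);
        double *g = &Gs[static_cast<size_t>(kl) * n_dense];
        if (w1 > 0 && w0 > 0) {
          for (int i = 0; i < n_dense; ++i) {
            const int m = cm[i];
            const double w = cw[i];
            g[i] += w1 * ((1 - w) * t1[m] + w * t1[m + 1]) +
                    w0 * ((1 - w) * t0[m] + w * t0[m + 1]);
          }
        } else if (w1 > 0) {
          for (int i = 0; i < n_dense; ++i) {
            const int m = cm[i];
            const double w = cw[i];
            g[i] += w1 * ((1 - w) * t1[m] + w * t1[m + 1]);
          }
        } else {
          for (int i = 0; i < n_dense; ++i) {
            const int m = cm[i];
            const double w = cw[i];
            g[i] += w0 * ((1 - w) * t0[m] + w * t0[m + 1]);
          }
        }
      }
    }
  }

  // stage 2: per-node interpolation positions, then one accumulation pass
  std::vector<int> jm(static_cast<size_t>(nact) * nmaf);
  std::vector<double> jw(static_cast<size_t>(nact) * nmaf);
  for (int s = 0; s < nact; ++s) {
    const int f = active[s];
    int *jms = &jm[static_cast<size_t>(s) * nmaf];
    double *jws = &jw[static_cast<size_t>(s) * nmaf];
    for (int m = 0; m < nmaf; ++m) {
      double x = (lnalpha(m, f) - amin[s]) / da[s];
      int j = static_cast<int>(std::floor(x));
      if (j < 0) { j = 0; x = 0.0; }
      else if (j > n_dense - 2) { j = n_dense - 2; x = n_dense - 1; }
      jms[m] = j;
      jws[m] = x - j;
    }
  }
  for (int kl = 0; kl < nkl; ++kl) {
    double *o = &out[static_cast<R_xlen_t>(kl) * nmaf];
    for (int s = 0; s < nact; ++s) {
      const double *g = &G[(static_cast<size_t>(s) * nkl + kl) * n_dense];
      const int *jms = &jm[static_cast<size_t>(s) * nmaf];
      const double *jws = &jw[static_cast<size_t>(s) * nmaf];
      for (int m = 0; m < nmaf; ++m) {
        const int j = jms[m];
        const double w = jws[m];
        o[m] += (1 - w) * g[j] + w * g[j + 1];
      }
    }
  }
  return out;
}

// Predictive probability of a positive response and one-step expected
// information gain (mutual information between the next response and the
// parameters) for a set of candidate stimuli.
//
//   p1  = sum_theta w(theta) P(x, theta)
//   mi  = sum_theta w(theta) phi(P) - phi(p1),  phi(p) = p log p + q log q
//
// The expected posterior entropy after observing the response at x equals
// H(current) - mi, so minimizing expected entropy is maximizing mi.
//
// P and PHI are [nodes x ncand_all] tables; cand are 1-based column
// indices. `active` (1-based) restricts the sums to nodes carrying
// non-negligible posterior mass; the caller guarantees the skipped nodes'
// total mass is numerically irrelevant.
// [[Rcpp::export]]
List cpp_score_candidates(NumericMatrix P, NumericMatrix PHI,
                          NumericVector w, IntegerVector cand,
                          Nullable<IntegerVector> active = R_NilValue) {
  const int n = P.nrow();
  const int nc = cand.size();
  NumericVector p1(nc), mi(nc);
  std::vector<int> idx;
  if (active.isNotNull()) {
    IntegerVector a(active);
    idx.reserve(a.size());
    for (int i = 0; i < a.size(); ++i) idx.push_back(a[i] - 1);
  }
  const bool indirect = !idx.empty();
  const int na = static_cast<int>(idx.size());
  for (int c = 0; c < nc; ++c) {
    const int col = cand[c] - 1;
    const double *pc = &P(0, col);
    const double *hc = &PHI(0, col);
    double s1 = 0.0, sh = 0.0;
    if (indirect) {
      for (int k = 0; k < na; ++k) {
        const int i = idx[k];
        s1 += w[i] * pc[i];
        sh += w[i] * hc[i];
      }
    } else {
      for (int i = 0; i < n; ++i) {
        s1 += w[i] * pc[i];
        sh += w[i] * hc[i];
      }
    }
    double q = 1.0 - s1;
    double phi1 = 0.0;
    if (s1 > 0) phi1 += s1 * std::log(s1);
    if (q > 0) phi1 += q * std::log(q);
    p1[c] = s1;
    mi[c] = sh - phi1;
  }
  return List::create(_["p1"] = p1, _["mi"] = mi);
}

// In-place softmax: given per-node log-likelihood `ll` and log-prior
// `lprior`, overwrite `ll` with the normalized posterior mass.
// [[Rcpp::export]]
void cpp_softmax_inplace(NumericVector ll, NumericVector lprior) {
  const R_xlen_t n = ll.size();
  double mx = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    ll[i] += lprior[i];
    if (ll[i] > mx) mx = ll[i];
  }
  if (!R_finite(mx)) stop("all grid nodes have zero posterior mass");
  double tot = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    ll[i] = std::exp(ll[i] - mx);
    tot += ll[i];
  }
  for (R_xlen_t i = 0; i < n; ++i) ll[i] /= tot;
}

// All marginal mass vectors of a dense 5-D probability array in one pass,
// using raw pointers and a blocked loop over the two fastest dimensions.
// [[Rcpp::export]]
List cpp_marginals(NumericVector mass, IntegerVector dims) {
  const int nd = dims.size();
  List out(nd);
  std::vector<double*> mp(nd);
  for (int d = 0; d < nd; ++d) {
    NumericVector v(dims[d]);
    out[d] = v;
    mp[d] = REAL(v);
  }
  const double *m = REAL(mass);
  const int n0 = dims[0];
  R_xlen_t pos = 0;
  std::vector<int> idx(nd, 0);
  const R_xlen_t nblocks = mass.size() / n0;
  for (R_xlen_t b = 0; b < nblocks; ++b) {
    double s = 0.0;
    double *m0 = mp[0];
    for (int i = 0; i < n0; ++i) {
      const double v = m[pos + i];
      m0[i] += v;
      s += v;
    }
    for (int d = 1; d < nd; ++d) mp[d][idx[d]] += s;
    pos += n0;
    int d = 1;
    while (d < nd && ++idx[d] == dims[d]) { idx[d] = 0; ++d; }
  }
  return out;
}

// Pack the [nodes x ncand] response-probability table into one interleaved
// single-precision blob: per candidate, n floats of P followed by n floats
// of phi(P) = P log P + (1-P) log(1-P), computed here so no full
// double-precision phi matrix is ever materialized. Selection only ranks
// candidates, so float precision is ample.
// [[Rcpp::export]]
RawVector cpp_pack_tables(NumericMatrix P) {
  const R_xlen_t n = P.nrow();
  const R_xlen_t nc = P.ncol();
  RawVector out(2 * n * nc * sizeof(float));
  float *f = reinterpret_cast<float *>(RAW(out));
  for (R_xlen_t c = 0; c < nc; ++c) {
    const double *pc = &P(0, c);
    float *block = f + 2 * n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double p = pc[i];
      block[i] = static_cast<float>(p);
      double phi = 0.0;
      if (p > 0) phi += p * std::log(p);
      if (p < 1) phi += (1 - p) * std::log1p(-p);
      block[n + i] = static_cast<float>(phi);
    }
  }
  return out;
}

// Candidate scoring against a packed float table (see cpp_pack_tables and
// cpp_score_candidates for the quantities). The posterior weights are
// converted to float once per call so the inner loops are pure
// single-precision streams; the resulting ~1e-5 relative error only ranks
// candidates and never enters the posterior.
// [[Rcpp::export]]
List cpp_score_candidates_packed(RawVector packed, int n, NumericVector w,
                                 IntegerVector cand,
                                 Nullable<IntegerVector> active = R_NilValue) {
  const float *f = reinterpret_cast<const float *>(RAW(packed));
  const int nc = cand.size();
  NumericVector p1(nc), mi(nc);
  std::vector<float> wf(n);
  for (int i = 0; i < n; ++i) wf[i] = static_cast<float>(w[i]);
  std::vector<int> idx;
  if (active.isNotNull()) {
    IntegerVector a(active);
    idx.reserve(a.size());
    for (int i = 0; i < a.size(); ++i) idx.push_back(a[i] - 1);
  }
  const bool indirect = !idx.empty();
  const int na = static_cast<int>(idx.size());
  for (int c = 0; c < nc; ++c) {
    const float *pc = f + 2 * static_cast<R_xlen_t>(n) * (cand[c] - 1);
    const float *hc = pc + n;
    float s1a = 0.0f, s1b = 0.0f, sha = 0.0f, shb = 0.0f;
    if (indirect) {
      for (int k = 0; k < na; ++k) {
        const int i = idx[k];
        s1a += wf[i] * pc[i];
        sha += wf[i] * hc[i];
      }
    } else {
      int i = 0;
      for (; i + 1 < n; i += 2) {
        s1a += wf[i] * pc[i];
        s1b += wf[i + 1] * pc[i + 1];
        sha += wf[i] * hc[i];
        shb += wf[i + 1] * hc[i + 1];
      }
      for (; i < n; ++i) {
        s1a += wf[i] * pc[i];
        sha += wf[i] * hc[i];
      }
    }
    const double s1 = static_cast<double>(s1a) + s1b;
    const double sh = static_cast<double>(sha) + shb;
    double q = 1.0 - s1;
    double phi1 = 0.0;
    if (s1 > 0) phi1 += s1 * std::log(s1);
    if (q > 0) phi1 += q * std::log(q);
    p1[c] = s1;
    mi[c] = sh - phi1;
  }
  return List::create(_["p1"] = p1, _["mi"] = mi);
}
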