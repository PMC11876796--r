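// Fused per-pair kernels for spatiotemporal causal attention.
// Pair lists are sorted by query; q_ptr is a 0-based cumulative count per
// query row.  All P-sized buffers use transposed (d x P) layout so each
// pair is one contiguous column.  Dense GEMMs (value projections, weight
// gradients) stay on the R side in BLAS; these kernels handle the
// irregular per-pair reductions.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scores, per-query softmax over the context, gate pre-activations and the
// message MLP's hidden layer, in one pass.
// QT, KT, A1T, B1T: d x R.  Returns alphaT (nh x P), h1T (d x P), pre (P).
// [[Rcpp::export]]
List sca_pairs_fwd_cpp(const NumericMatrix& QT, const NumericMatrix& KT,
                       const NumericMatrix& A1T, const NumericMatrix& B1T,
                       const NumericVector& b1, const NumericVector& aq,
                       const NumericVector& ak, const IntegerVector& qi,
                       const IntegerVector& ki, const NumericVector& q_ptr,
                       int nh, bool with_gate) {
  const int P = qi.size();
  const int R = QT.ncol();
  const int d = QT.nrow();
  const int dh = d / nh;
  const double inv_sqrt_dh = 1.0 / std::sqrt((double) dh);
  NumericMatrix alphaT(nh, P);
  NumericMatrix h1T(d, P);
  NumericVector pre(with_gate ? P : 0);
  const double* qt = &QT(0, 0);
  const double* kt = &KT(0, 0);
  const double* a1 = &A1T(0, 0);
  const double* bt = &B1T(0, 0);
  double* al = &alphaT(0, 0);
  double* h1 = &h1T(0, 0);
  std::vector<double> smax(nh), ssum(nh);
  for (int q = 0; q < R; ++q) {
    const int lo = (int) q_ptr[q];
    const int hi = (int) q_ptr[q + 1];
    if (lo == hi) continue;
    const double* qc = qt + (size_t) q * d;
    for (int h = 0; h < nh; ++h) smax[h] = -1e300;
    for (int p = lo; p < hi; ++p) {
      const double* kc = kt + (size_t) (ki[p] - 1) * d;
      double* ac = al + (size_t) p * nh;
      for (int h = 0; h < nh; ++h) {
        double s = 0.0;
        const int c0 = h * dh;
        for (int c = c0; c < c0 + dh; ++c) s += qc[c] * kc[c];
        s *= inv_sqrt_dh;
        ac[h] = s;
        if (s > smax[h]) smax[h] = s;
      }
    }
    for (int h = 0; h < nh; ++h) ssum[h] = 0.0;
    for (int p = lo; p < hi; ++p) {
      double* ac = al + (size_t) p * nh;
      for (int h = 0; h < nh; ++h) {
        const double e = std::exp(ac[h] - smax[h]);
        ac[h] = e;
        ssum[h] += e;
      }
    }
    for (int h = 0; h < nh; ++h) ssum[h] = 1.0 / ssum[h];
    for (int p = lo; p < hi; ++p) {
      double* ac = al + (size_t) p * nh;
      for (int h = 0; h < nh; ++h) ac[h] *= ssum[h];
    }
  }
  for (int p = 0; p < P; ++p) {
    const int qr = qi[p] - 1;
    const int kr = ki[p] - 1;
    const double* acq = a1 + (size_t) qr * d;
    const double* bck = bt + (size_t) kr * d;
    double* hc = h1 + (size_t) p * d;
    for (int c = 0; c < d; ++c) {
      const double z = acq[c] + bck[c] + b1[c];
      hc[c] = z > 0 ? z : 0.0;
    }
    if (with_gate) pre[p] = aq[qr] + ak[kr];
  }
  return List::create(_["alphaT"] = alphaT, _["h1T"] = h1T, _["pre"] = pre);
}

// Scatter-add columns of XT (d x P) into a (d x n) matrix by 1-based index.
// [[Rcpp::export]]
NumericMatrix accum_cols_cpp(const NumericMatrix& XT, const IntegerVector& idx,
                             int n) {
  const int P = XT.ncol();
  const int d = XT.nrow();
  NumericMatrix out(d, n);
  const double* x = &XT(0, 0);
  double* o = &out(0, 0);
  for (int p = 0; p < P; ++p) {
    const double* xc = x + (size_t) p * d;
    double* oc = o + (size_t) (idx[p] - 1) * d;
    for (int c = 0; c < d; ++c) oc[c] += xc[c];
  }
  return out;
}

// Scatter-add a vector by 1-based index.
// [[Rcpp::export]]
NumericVector accum_vec_cpp(const NumericVector& x, const IntegerVector& idx,
                            int n) {
  NumericVector out(n);
  for (int p = 0; p < x.size(); ++p) out[idx[p] - 1] += x[p];
  return out;
}

// In-place row softmax (used by the prompt decoder; S is R x NP).
// [[Rcpp::export]]
void row_softmax_inplace_cpp(NumericMatrix S) {
  const int n = S.nrow();
  const int m = S.ncol();
  double* s = &S(0, 0);
  for (int i = 0; i < n; ++i) {
    double mx = -1e300;
    for (int j = 0; j < m; ++j) {
      const double v = s[(size_t) j * n + i];
      if (v > mx) mx = v;
    }
    double tot = 0.0;
    for (int j = 0; j < m; ++j) {
      const double e = std::exp(s[(size_t) j * n + i] - mx);
      s[(size_t) j * n + i] = e;
      tot += e;
    }
    const double inv = 1.0 / tot;
    for (int j = 0; j < m; ++j) s[(size_t) j * n + i] *= inv;
  }
}

// Row-softmax backward in place: gP <- P * (gP - rowSums(gP * P)).
// [[Rcpp::export]]
void row_softmax_bwd_inplace_cpp(NumericMatrix gP, const NumericMatrix& P) {
  const int n = gP.nrow();
  const int m = gP.ncol();
  double* g = &gP(0, 0);
  const double* p = &P(0, 0);
  std::vector<double> acc(n, 0.0);
  for (int j = 0; j < m; ++j) {
    const size_t off = (size_t) j * n;
    for (int i = 0; i < n; ++i) acc[i] += g[off + i] * p[off + i];
  }
  for (int j = 0; j < m; ++j) {
    const size_t off = (size_t) j * n;
    for (int i = 0; i < n; ++i) g[off + i] = p[off + i] * (g[off + i] - acc[i]);
  }
}

// Binary Gumbel-Softmax gate: rho = clamp(sigmoid(pre)); train mode draws
// beta = sigmoid((logit(rho) + g1 - g2)/tau), eval mode hard-thresholds.
// [[Rcpp::export]]
List gate_fwd_cpp(const NumericVector& pre, double tau,
                  const NumericVector& u1, const NumericVector& u2,
                  bool train, double rho_eps) {
  const int P = pre.size();
  NumericVector rho(P), beta(P);
  for (int p = 0; p < P; ++p) {
    double r = 1.0 / (1.0 + std::exp(-pre[p]));
    if (r < rho_eps) r = rho_eps;
    if (r > 1.0 - rho_eps) r = 1.0 - rho_eps;
    rho[p] = r;
    if (train) {
      double a = u1[p], b = u2[p];
      if (a < 1e-6) a = 1e-6; if (a > 1.0 - 1e-6) a = 1.0 - 1e-6;
      if (b < 1e-6) b = 1e-6; if (b > 1.0 - 1e-6) b = 1.0 - 1e-6;
      const double g1 = -std::log(-std::log(a));
      const double g2 = -std::log(-std::log(b));
      const double z = (std::log(r) - std::log1p(-r) + g1 - g2) / tau;
      beta[p] = 1.0 / (1.0 + std::exp(-z));
    } else {
      beta[p] = r >= 0.5 ? 1.0 : 0.0;
    }
  }
  return List::create(_["rho"] = rho, _["beta"] = beta);
}

// Gate backward: gpre = (gbeta * beta(1-beta)/(tau rho(1-rho)) + gextra)
//                * rho(1-rho).
// [[Rcpp::export]]
NumericVector gate_bwd_cpp(const NumericVector& gbeta,
                           const NumericVector& rho,
                           const NumericVector& beta, double tau,
                           double g_rho_extra) {
  const int P = gbeta.size();
  NumericVector gpre(P);
  for (int p = 0; p < P; ++p) {
    const double rr = rho[p] * (1.0 - rho[p]);
    const double grho = gbeta[p] * beta[p] * (1.0 - beta[p]) / (tau * rr) +
      g_rho_extra;
    gpre[p] = grho * rr;
  }
  return gpre;
}

// Blocked in-place row softmax: S is R x (nb*bs); softmax per row within
// each column block of width bs.
// [[Rcpp::export]]
void row_softmax_blocked_cpp(NumericMatrix S, int bs) {
  const int n = S.nrow();
  const int m = S.ncol();
  const int nb = m / bs;
  double* s = &S(0, 0);
  std::vector<double> mx(n), tot(n);
  for (int b = 0; b < nb; ++b) {
    const size_t off0 = (size_t) b * bs * n;
    std::fill(mx.begin(), mx.end(), -1e300);
    for (int j = 0; j < bs; ++j) {
      const double* col = s + off0 + (size_t) j * n;
      for (int i = 0; i < n; ++i) if (col[i] > mx[i]) mx[i] = col[i];
    }
    std::fill(tot.begin(), tot.end(), 0.0);
    for (int j = 0; j < bs; ++j) {
      double* col = s + off0 + (size_t) j * n;
      for (int i = 0; i < n; ++i) {
        const double e = std::exp(col[i] - mx[i]);
        col[i] = e;
        tot[i] += e;
      }
    }
    for (int i = 0; i < n; ++i) tot[i] = 1.0 / tot[i];
    for (int j = 0; j < bs; ++j) {
      double* col = s + off0 + (size_t) j * n;
      for (int i = 0; i < n; ++i) col[i] *= tot[i];
    }
  }
}

// Blocked row-softmax backward in place: per block,
// gS <- P * (gS - rowSums(gS * P)) * scale.
// [[Rcpp::export]]
void row_softmax_bwd_blocked_cpp(NumericMatrix gS, const NumericMatrix& P,
                                 int bs, double scale) {
  const int n = gS.nrow();
  const int m = gS.ncol();
  const int nb = m / bs;
  double* g = &gS(0, 0);
  const double* p = &P(0, 0);
  std::vector<double> acc(n);
  for (int b = 0; b < nb; ++b) {
    const size_t off0 = (size_t) b * bs * n;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < bs; ++j) {
      const size_t off = off0 + (size_t) j * n;
      for (int i = 0; i < n; ++i) acc[i] += g[off + i] * p[off + i];
    }
    for (int j = 0; j < bs; ++j) {
      const size_t off = off0 + (size_t) j * n;
      for (int i = 0; i < n; ++i)
        g[off + i] = p[off + i] * (g[off + i] - acc[i]) * scale;
    }
  }
}

// Head-weighted aggregation of the message hidden layer:
// AggT[(h)*d + e, q] = sum_p beta_p * alpha_ph * h1T[e, p];  ZT[h, q].
// [[Rcpp::export]]
List sca_agg_cpp(const NumericMatrix& h1T, const NumericMatrix& alphaT,
                 const NumericVector& beta, const NumericVector& q_ptr,
                 int n_rows, int nh) {
  const int d = h1T.nrow();
  NumericMatrix AggT(d * nh, n_rows);
  NumericMatrix ZT(nh, n_rows);
  const double* h1 = &h1T(0, 0);
  const double* al = &alphaT(0, 0);
  for (int q = 0; q < n_rows; ++q) {
    const int lo = (int) q_ptr[q];
    const int hi = (int) q_ptr[q + 1];
    double* ag = &AggT(0, q);
    double* zc = &ZT(0, q);
    for (int p = lo; p < hi; ++p) {
      const double b = beta[p];
      if (b == 0.0) continue;
      const double* hc = h1 + (size_t) p * d;
      const double* ac = al + (size_t) p * nh;
      for (int h = 0; h < nh; ++h) {
        const double w = b * ac[h];
        if (w == 0.0) continue;
        zc[h] += w;
        double* agh = ag + (size_t) h * d;
        for (int e = 0; e < d; ++e) agh[e] += w * hc[e];
      }
    }
  }
  return List::create(_["AggT"] = AggT, _["ZT"] = ZT);
}

// Backward through the aggregation, attention softmax and gate weights.
// Gstack[(h)*d + e, q] = (W2[cols_h, ]' gnum[q, cols_h])[e];
// gZb[h, q] = gZ[h, q] + b2[cols_h] . gnum[q, cols_h].
// Returns gh1T (d x P), gbeta (P), and accumulated gQT, gKT (d x R).
// [[Rcpp::export]]
List sca_agg_bwd_cpp(const NumericMatrix& h1T, const NumericMatrix& alphaT,
                     const NumericVector& beta, const NumericMatrix& Gstack,
                     const NumericMatrix& gZb, const NumericMatrix& QT,
                     const NumericMatrix& KT, const IntegerVector& qi,
                     const IntegerVector& ki, const NumericVector& q_ptr,
                     int nh) {
  const int P = qi.size();
  const int R = QT.ncol();
  const int d = QT.nrow();
  const int dh = d / nh;
  const double inv_sqrt_dh = 1.0 / std::sqrt((double) dh);
  NumericMatrix gh1T(d, P);
  NumericVector gbeta(P);
  NumericMatrix gQT(d, R);
  NumericMatrix gKT(d, R);
  NumericMatrix gaT(nh, P);   // galpha scratch
  const double* h1 = &h1T(0, 0);
  const double* al = &alphaT(0, 0);
  const double* qt = &QT(0, 0);
  const double* kt = &KT(0, 0);
  double* gh = &gh1T(0, 0);
  double* ga = &gaT(0, 0);
  std::vector<double> ssum(nh);
  for (int q = 0; q < R; ++q) {
    const int lo = (int) q_ptr[q];
    const int hi = (int) q_ptr[q + 1];
    if (lo == hi) continue;
    const double* gs = &Gstack(0, q);
    const double* gzc = &gZb(0, q);
    const double* qc = qt + (size_t) q * d;
    double* gqc = &gQT(0, q);
    for (int h = 0; h < nh; ++h) ssum[h] = 0.0;
    for (int p = lo; p < hi; ++p) {
      const double b = beta[p];
      const double* hc = h1 + (size_t) p * d;
      const double* ac = al + (size_t) p * nh;
      double* ghc = gh + (size_t) p * d;
      double* gac = ga + (size_t) p * nh;
      double gb = 0.0;
      for (int h = 0; h < nh; ++h) {
        const double* gsh = gs + (size_t) h * d;
        double gw = gzc[h];
        for (int e = 0; e < d; ++e) gw += hc[e] * gsh[e];
        const double w = b * ac[h];
        for (int e = 0; e < d; ++e) ghc[e] += w * gsh[e];
        const double galpha = b * gw;
        gac[h] = galpha;
        gb += ac[h] * gw;
        ssum[h] += ac[h] * galpha;
      }
      gbeta[p] = gb;
    }
    for (int p = lo; p < hi; ++p) {
      const int kr = ki[p] - 1;
      const double* kc = kt + (size_t) kr * d;
      double* gkc = &gKT(0, kr);
      const double* ac = al + (size_t) p * nh;
      const double* gac = ga + (size_t) p * nh;
      for (int h = 0; h < nh; ++h) {
        const double gscore = ac[h] * (gac[h] - ssum[h]) * inv_sqrt_dh;
        const int c0 = h * dh;
        for (int c = c0; c < c0 + dh; ++c) {
          gqc[c] += gscore * kc[c];
          gkc[c] += gscore * qc[c];
        }
      }
    }
  }
  return List::create(_["gh1T"] = gh1T, _["gbeta"] = gbeta, _["gQT"] = gQT,
                      _["gKT"] = gKT);
}
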