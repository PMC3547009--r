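#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Multichannel cascaded IIR machinery: all channels advance together
// through time so memory access over the channels x samples matrix is
// purely sequential. State is held channel-fastest so the channel loop
// vectorizes.
struct CascadeState {
  int nch, n1, n2;                        // filter orders (taps - 1)
  std::vector<double> b1, a1, b2, a2;     // coefficients
  std::vector<double> z1, z2;             // states, (order x nch)
  CascadeState(int nch_, NumericVector B1, NumericVector A1,
               NumericVector B2, NumericVector A2)
    : nch(nch_), n1(B1.size() - 1), n2(B2.size() - 1),
      b1(B1.begin(), B1.end()), a1(A1.begin(), A1.end()),
      b2(B2.begin(), B2.end()), a2(A2.begin(), A2.end()) {
    reset();
  }
  void reset() {
    z1.assign((R_xlen_t)n1 * nch, 0.0);
    z2.assign((R_xlen_t)n2 * nch, 0.0);
  }
  // advance one time step: x -> y (may alias), both length nch
  inline void step(const double *x, double *y) {
    for (int c = 0; c < nch; ++c) {
      double xi = x[c];
      double v = b1[0] * xi + z1[c];
      for (int k = 1; k < n1; ++k)
        z1[(k - 1) * nch + c] = b1[k] * xi + z1[k * nch + c] - a1[k] * v;
      z1[(n1 - 1) * nch + c] = b1[n1] * xi - a1[n1] * v;
      double w = b2[0] * v + z2[c];
      for (int k = 1; k < n2; ++k)
        z2[(k - 1) * nch + c] = b2[k] * v + z2[k * nch + c] - a2[k] * w;
      z2[(n2 - 1) * nch + c] = b2[n2] * v - a2[n2] * w;
      y[c] = w;
    }
  }
};

// Zero-phase filtering of each row through two cascaded filters (high-pass
// then low-pass), applied forward then backward, with odd-reflection
// padding of `npad` samples at both ends. Two sequential passes over the
// matrix; the padding columns are synthesized on the fly and the filtered
// right-hand pad is buffered to warm the backward state.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericMatrix x, NumericVector b1,
                                NumericVector a1, NumericVector b2,
                                NumericVector a2, int npad) {
  int nch = x.nrow(), ns = x.ncol();
  if (npad > ns - 1) npad = ns - 1;
  NumericMatrix out(nch, ns);
  const double *xp = REAL(x);
  double *op = REAL(out);
  CascadeState st(nch, b1, a1, b2, a2);
  std::vector<double> col(nch), sink(nch);
  std::vector<double> rpad((R_xlen_t)std::max(npad, 1) * nch);
  // forward: left pad (discard), data, right pad (buffer)
  for (int i = npad; i >= 1; --i) {
    const double *e0 = xp;                // x[, 0] and x[, i]
    const double *ei = xp + (R_xlen_t)i * nch;
    for (int c = 0; c < nch; ++c) col[c] = 2 * e0[c] - ei[c];
    st.step(col.data(), sink.data());
  }
  for (int i = 0; i < ns; ++i)
    st.step(xp + (R_xlen_t)i * nch, op + (R_xlen_t)i * nch);
  for (int i = 1; i <= npad; ++i) {
    const double *en = xp + (R_xlen_t)(ns - 1) * nch;
    const double *ei = xp + (R_xlen_t)(ns - 1 - i) * nch;
    for (int c = 0; c < nch; ++c) col[c] = 2 * en[c] - ei[c];
    st.step(col.data(), rpad.data() + (R_xlen_t)(i - 1) * nch);
  }
  // backward: filtered right pad (discard), data in place, stop at 0
  st.reset();
  for (int i = npad - 1; i >= 0; --i)
    st.step(rpad.data() + (R_xlen_t)i * nch, sink.data());
  for (int i = ns - 1; i >= 0; --i) {
    double *oi = op + (R_xlen_t)i * nch;
    st.step(oi, oi);
  }
  rownames(out) = rownames(x);
  return out;
}

// Cut epochs around event samples (1-based). Returns (nch x nt x ntr).
// [[Rcpp::export]]
NumericVector cpp_epoch_build(NumericMatrix data, IntegerVector events,
                              int npre, int npost) {
  int nch = data.nrow();
  int nt = npre + npost, ntr = events.size();
  NumericVector out(Dimension(nch, nt, ntr));
  const double *d = REAL(data);
  double *o = REAL(out);
  for (int j = 0; j < ntr; ++j) {
    R_xlen_t start = events[j] - 1 - npre; // 0-based first sample
    std::copy(d + start * nch, d + (start + nt) * nch,
              o + (R_xlen_t)j * nch * nt);
  }
  return out;
}

// In-place per-(channel, trial) baseline subtraction (mean of first `npre`
// samples) followed by mean-mastoid re-referencing (0-based mastoid rows).
// [[Rcpp::export]]
NumericVector cpp_baseline_reref(NumericVector epochs, int nch, int nt,
                                 int ntr, int npre, int m1, int m2,
                                 bool do_baseline, bool do_reref) {
  double *e = REAL(epochs);
  std::vector<double> bmean(nch), ref(nt);
  for (int j = 0; j < ntr; ++j) {
    double *tr = e + (R_xlen_t)j * nch * nt;
    if (do_baseline) {
      std::fill(bmean.begin(), bmean.end(), 0.0);
      for (int t = 0; t < npre; ++t) {
        const double *col = tr + (R_xlen_t)t * nch;
        for (int c = 0; c < nch; ++c) bmean[c] += col[c];
      }
      for (int c = 0; c < nch; ++c) bmean[c] /= npre;
      for (int t = 0; t < nt; ++t) {
        double *col = tr + (R_xlen_t)t * nch;
        for (int c = 0; c < nch; ++c) col[c] -= bmean[c];
      }
    }
    if (do_reref) {
      for (int t = 0; t < nt; ++t) {
        double *col = tr + (R_xlen_t)t * nch;
        double r = 0.5 * (col[m1] + col[m2]);
        for (int c = 0; c < nch; ++c) col[c] -= r;
      }
    }
  }
  return epochs;
}

// Combined artifact scan. One sweep accumulates, per scanned channel and
// trial: absolute maximum, least-squares linear span and kurtosis (from raw
// power sums), and, per (channel, time), across-trial sums for the
// improbable-data rule. A second sweep flags improbable trials. `full`
// FALSE computes the absolute maximum only.
// [[Rcpp::export]]
List cpp_artifact_scan(NumericVector epochs, int nch, int nt, int ntr,
                       IntegerVector channels, bool full, double ksd) {
  int m = channels.size();
  NumericMatrix absmax(m, ntr);
  NumericMatrix span(full ? m : 0, full ? ntr : 0);
  NumericMatrix kurt(full ? m : 0, full ? ntr : 0);
  const double *e = REAL(epochs);
  std::vector<int> ci(m);
  for (int k = 0; k < m; ++k) ci[k] = channels[k] - 1;
  double tmean = (nt - 1) / 2.0;
  double denom = 0.0;
  for (int t = 0; t < nt; ++t) denom += (t - tmean) * (t - tmean);
  std::vector<double> s1t, s2t;
  if (full && ksd > 0) {
    s1t.assign((R_xlen_t)m * nt, 0.0);
    s2t.assign((R_xlen_t)m * nt, 0.0);
  }
  for (int j = 0; j < ntr; ++j) {
    const double *tr = e + (R_xlen_t)j * nch * nt;
    for (int k = 0; k < m; ++k) {
      int c = ci[k];
      double mx = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0, s4 = 0.0, st = 0.0;
      if (full) {
        for (int t = 0; t < nt; ++t) {
          double v = tr[c + (R_xlen_t)t * nch];
          double av = std::fabs(v);
          if (av > mx) mx = av;
          double v2 = v * v;
          s1 += v;
          s2 += v2;
          s3 += v2 * v;
          s4 += v2 * v2;
          st += v * (t - tmean);
          if (ksd > 0) {
            s1t[k + (R_xlen_t)t * m] += v;
            s2t[k + (R_xlen_t)t * m] += v2;
          }
        }
        double mean = s1 / nt;
        double m2 = s2 / nt - mean * mean;
        double m4 = s4 / nt - 4 * mean * s3 / nt + 6 * mean * mean * s2 / nt -
          3 * mean * mean * mean * mean;
        span(k, j) = std::fabs(st / denom) * (nt - 1);
        kurt(k, j) = m2 > 0 ? m4 / (m2 * m2) : 0.0;
      } else {
        for (int t = 0; t < nt; ++t) {
          double av = std::fabs(tr[c + (R_xlen_t)t * nch]);
          if (av > mx) mx = av;
        }
      }
      absmax(k, j) = mx;
    }
  }
  LogicalVector improbable(full && ksd > 0 ? ntr : 0);
  if (full && ksd > 0 && ntr >= 3) {
    std::vector<double> lo((R_xlen_t)m * nt), hi((R_xlen_t)m * nt);
    for (R_xlen_t i = 0; i < (R_xlen_t)m * nt; ++i) {
      double mu = s1t[i] / ntr;
      double var = (s2t[i] - ntr * mu * mu) / (ntr - 1);
      double sd = var > 0 ? std::sqrt(var) : 0.0;
      if (sd <= 0) { lo[i] = R_NegInf; hi[i] = R_PosInf; }
      else { lo[i] = mu - ksd * sd; hi[i] = mu + ksd * sd; }
    }
    for (int j = 0; j < ntr; ++j) {
      const double *tr = e + (R_xlen_t)j * nch * nt;
      bool f = false;
      for (int t = 0; t < nt && !f; ++t) {
        const double *col = tr + (R_xlen_t)t * nch;
        const double *lop = lo.data() + (R_xlen_t)t * m;
        const double *hip = hi.data() + (R_xlen_t)t * m;
        for (int k = 0; k < m; ++k) {
          double v = col[ci[k]];
          if (v < lop[k] || v > hip[k]) { f = true; break; }
        }
      }
      improbable[j] = f;
    }
  }
  return List::create(_["absmax"] = absmax, _["span"] = span,
                      _["kurt"] = kurt, _["improbable"] = improbable);
}

// In-place rank-k update: data += topo %*% course (data nch x ns,
// topo nch x k, course k x ns). Avoids the two full-size temporaries an
// R-level product-and-add would allocate.
// [[Rcpp::export]]
NumericMatrix cpp_add_outer(NumericMatrix data, NumericMatrix topo,
                            NumericMatrix course) {
  int nch = data.nrow();
  R_xlen_t ns = data.ncol();
  int k = topo.ncol();
  double *d = REAL(data);
  const double *tp = REAL(topo);
  const double *cp = REAL(course);
  for (R_xlen_t i = 0; i < ns; ++i) {
    const double *crs = cp + i * k;
    double *col = d + i * nch;
    for (int q = 0; q < k; ++q) {
      double w = crs[q];
      if (w == 0.0) continue;
      const double *tq = tp + (R_xlen_t)q * nch;
      for (int c = 0; c < nch; ++c) col[c] += w * tq[c];
    }
  }
  return data;
}

// Category averages: mean over selected trials (1-based indices) of the
// (nch x nt x ntr) array, returned as nch x nt.
// [[Rcpp::export]]
NumericMatrix cpp_trial_mean(NumericVector epochs, int nch, int nt, int ntr,
                             IntegerVector trials) {
  NumericMatrix out(nch, nt);
  double *o = REAL(out);
  const double *e = REAL(epochs);
  int k = trials.size();
  for (int j = 0; j < k; ++j) {
    const double *tr = e + (R_xlen_t)(trials[j] - 1) * nch * nt;
    for (R_xlen_t i = 0; i < (R_xlen_t)nch * nt; ++i) o[i] += tr[i];
  }
  for (R_xlen_t i = 0; i < (R_xlen_t)nch * nt; ++i) o[i] /= k;
  return out;
}
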