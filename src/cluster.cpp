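#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of supra-threshold points on a
// channels x time grid. Adjacency: (c, t) ~ (c, t±1) and (c, t) ~ (c', t)
// for spatially neighbouring channels c'. Positive and negative points are
// clustered separately (sign = +1 or -1).

static void label_one_sign(const double *t, int C, int T, double thr,
                           const std::vector<std::vector<int>> &nbr,
                           int sign, std::vector<int> &labels,
                           std::vector<double> &masses) {
  // labels: 0 = not supra-threshold (for this sign), k>0 = cluster id
  std::fill(labels.begin(), labels.end(), 0);
  masses.clear();
  std::vector<int> stack;
  int next = 0;
  for (int p = 0; p < C * T; ++p) {
    double v = sign * t[p];
    if (v <= thr || labels[p] != 0) continue;
    ++next;
    double mass = 0.0;
    stack.push_back(p);
    labels[p] = next;
    while (!stack.empty()) {
      int q = stack.back();
      stack.pop_back();
      mass += t[q];
      int c = q % C, s = q / C; // column-major: rows = channels
      // temporal neighbours
      if (s > 0) {
        int r = q - C;
        if (labels[r] == 0 && sign * t[r] > thr) { labels[r] = next; stack.push_back(r); }
      }
      if (s < T - 1) {
        int r = q + C;
        if (labels[r] == 0 && sign * t[r] > thr) { labels[r] = next; stack.push_back(r); }
      }
      // spatial neighbours at the same sample
      for (size_t k = 0; k < nbr[c].size(); ++k) {
        int r = nbr[c][k] + s * C;
        if (labels[r] == 0 && sign * t[r] > thr) { labels[r] = next; stack.push_back(r); }
      }
    }
    masses.push_back(mass);
  }
}

static std::vector<std::vector<int>> as_nbr(List neighbors) {
  int C = neighbors.size();
  std::vector<std::vector<int>> nbr(C);
  for (int c = 0; c < C; ++c) {
    IntegerVector v = neighbors[c]; // 1-based channel indices
    nbr[c].assign(v.begin(), v.end());
    for (size_t k = 0; k < nbr[c].size(); ++k) nbr[c][k] -= 1;
  }
  return nbr;
}

// [[Rcpp::export]]
List cpp_label_clusters(NumericMatrix tmap, double threshold, List neighbors,
                        int sign) {
  int C = tmap.nrow(), T = tmap.ncol();
  std::vector<std::vector<int>> nbr = as_nbr(neighbors);
  std::vector<int> labels(C * T);
  std::vector<double> masses;
  label_one_sign(REAL(tmap), C, T, threshold, nbr, sign, labels, masses);
  IntegerMatrix lab(C, T);
  std::copy(labels.begin(), labels.end(), lab.begin());
  return List::create(_["labels"] = lab,
                      _["masses"] = NumericVector(masses.begin(), masses.end()));
}

// For each sign-flip assignment: paired t-map over all points, then the
// maximum positive and minimum negative cluster mass. M is P x n_perm
// (P = C*T, channels fastest) of per-point means under each assignment
// (computed in R by one BLAS product crossprod(D, flips)/n), ss =
// colSums(D^2), which is invariant under sign flips.
// [[Rcpp::export]]
NumericMatrix cpp_perm_extreme_mass(NumericMatrix M, NumericVector ss,
                                    int n, double t_threshold,
                                    List neighbors, int C, int T) {
  int P = M.nrow(), nperm = M.ncol();
  if (P != C * T) stop("P != C*T");
  std::vector<std::vector<int>> nbr = as_nbr(neighbors);
  NumericMatrix out(nperm, 2);
  std::vector<double> tmap(P);
  std::vector<int> labels(P);
  std::vector<double> masses;
  const double *mp = REAL(M);
  const double *s2 = REAL(ss);
  for (int b = 0; b < nperm; ++b) {
    const double *mcol = mp + (R_xlen_t)b * P;
    for (int p = 0; p < P; ++p) {
      double m = mcol[p];
      double var = (s2[p] - n * m * m) / (n - 1);
      // zero across-participant variance: no evidence either way
      tmap[p] = var > 0 ? m / std::sqrt(var / n) : 0.0;
    }
    double best_pos = 0.0, best_neg = 0.0;
    label_one_sign(tmap.data(), C, T, t_threshold, nbr, +1, labels, masses);
    for (size_t k = 0; k < masses.size(); ++k)
      if (masses[k] > best_pos) best_pos = masses[k];
    label_one_sign(tmap.data(), C, T, t_threshold, nbr, -1, labels, masses);
    for (size_t k = 0; k < masses.size(); ++k)
      if (masses[k] < best_neg) best_neg = masses[k];
    out(b, 0) = best_pos;
    out(b, 1) = best_neg;
  }
  return out;
}
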