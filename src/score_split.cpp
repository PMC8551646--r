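#include <Rcpp.h>
using namespace Rcpp;

// Best admissible bipartition of one categorical covariate at a node of
// the differential-effect search.
//
// idx: 1-based record indices of the node; x: level codes (NA = missing);
// y: outcome; g: contrast indicator (0 = reference group); nlev: declared
// level count; ordinal: threshold splits in level order vs. subset
// enumeration; sgn: disadvantage sign; D: centering offset. A candidate
// is admissible when each child holds >= min_node records per contrast
// group (and, for binary outcomes, >= min_events events per arm) and both
// child standard errors are positive. The criterion is
// p = 2 * min(1 - Phi(z1), 1 - Phi(z2)) with z = (sgn*(m2-m1) - D) / se.
// Enumeration order (thresholds ascending; subset bitmasks ascending over
// the first ko-1 observed levels) fixes tie-breaks deterministically.
//
// Returns NULL when no admissible candidate exists, else a list with the
// best candidate's criterion value, the admissible-candidate count, both
// child z's, the promising (larger-z) side, and that child's summaries.
// [[Rcpp::export]]
SEXP score_split_cpp(IntegerVector idx, IntegerVector x, NumericVector y,
                     IntegerVector g, int nlev, bool ordinal, bool binary,
                     double sgn, double D, double min_node,
                     double min_events) {
  std::vector<double> n(2 * nlev, 0.0), s(2 * nlev, 0.0), q(2 * nlev, 0.0);
  const int m = idx.size();
  for (int i = 0; i < m; ++i) {
    const int r = idx[i] - 1;
    const int xv = x[r];
    if (xv == NA_INTEGER) continue;
    const int c = (xv - 1) + nlev * g[r];
    const double yv = y[r];
    n[c] += 1.0; s[c] += yv; q[c] += yv * yv;
  }
  std::vector<int> obs;
  for (int l = 0; l < nlev; ++l) {
    if (n[l] + n[nlev + l] > 0) obs.push_back(l);
  }
  const int ko = (int) obs.size();
  if (ko < 2) return R_NilValue;

  double tN[2] = {0, 0}, tS[2] = {0, 0}, tQ[2] = {0, 0};
  for (int l = 0; l < nlev; ++l) {
    tN[0] += n[l]; tS[0] += s[l]; tQ[0] += q[l];
    tN[1] += n[nlev + l]; tS[1] += s[nlev + l]; tQ[1] += q[nlev + l];
  }

  auto zstat = [&](const double N1, const double N2, const double S1,
                   const double S2, const double Q1, const double Q2,
                   double &se2, double &m1, double &m2) -> double {
    m1 = S1 / N1; m2 = S2 / N2;
    if (binary) {
      se2 = m1 * (1 - m1) / N1 + m2 * (1 - m2) / N2;
    } else {
      const double v1 = (Q1 - S1 * S1 / N1) / std::max(N1 - 1.0, 1.0);
      const double v2 = (Q2 - S2 * S2 / N2) / std::max(N2 - 1.0, 1.0);
      se2 = v1 / N1 + v2 / N2;
    }
    if (!(se2 > 0)) return R_NegInf;
    return (sgn * (m2 - m1) - D) / std::sqrt(se2);
  };

  const long ncomb = ordinal ? (ko - 1) : ((1L << (ko - 1)) - 1L);
  double best_p = R_PosInf;
  int ncand = 0;
  long best_c = -1;
  double bz1 = 0, bz2 = 0, bn[4] = {0, 0, 0, 0};
  double bm[4] = {0, 0, 0, 0}, bse2[2] = {0, 0};

  double cN[2] = {0, 0}, cS[2] = {0, 0}, cQ[2] = {0, 0};
  for (long c = 1; c <= ncomb; ++c) {
    if (ordinal) {
      const int l = obs[c - 1];             // accumulate levels <= threshold
      cN[0] += n[l]; cS[0] += s[l]; cQ[0] += q[l];
      cN[1] += n[nlev + l]; cS[1] += s[nlev + l]; cQ[1] += q[nlev + l];
    } else {
      cN[0] = cN[1] = cS[0] = cS[1] = cQ[0] = cQ[1] = 0;
      for (int j = 0; j < ko - 1; ++j) {
        if (c & (1L << j)) {
          const int l = obs[j];
          cN[0] += n[l]; cS[0] += s[l]; cQ[0] += q[l];
          cN[1] += n[nlev + l]; cS[1] += s[nlev + l]; cQ[1] += q[nlev + l];
        }
      }
    }
    const double dN[2] = {tN[0] - cN[0], tN[1] - cN[1]};
    const double dS[2] = {tS[0] - cS[0], tS[1] - cS[1]};
    const double dQ[2] = {tQ[0] - cQ[0], tQ[1] - cQ[1]};

    if (std::min(std::min(cN[0], cN[1]), std::min(dN[0], dN[1])) < min_node)
      continue;
    if (binary &&
        std::min(std::min(cS[0], cS[1]), std::min(dS[0], dS[1])) < min_events)
      continue;

    double se2a, se2b, m1a, m2a, m1b, m2b;
    const double z1 = zstat(cN[0], cN[1], cS[0], cS[1], cQ[0], cQ[1],
                            se2a, m1a, m2a);
    const double z2 = zstat(dN[0], dN[1], dS[0], dS[1], dQ[0], dQ[1],
                            se2b, m1b, m2b);
    if (!(se2a > 0) || !(se2b > 0)) continue;
    ++ncand;

    double p = 2.0 * R::pnorm(std::max(z1, z2), 0.0, 1.0, 0, 0);
    if (p > 1.0) p = 1.0;
    if (p < DBL_MIN) p = DBL_MIN;
    if (p < best_p) {
      best_p = p; best_c = c; bz1 = z1; bz2 = z2;
      bn[0] = cN[0]; bn[1] = cN[1]; bn[2] = dN[0]; bn[3] = dN[1];
      bm[0] = m1a; bm[1] = m2a; bm[2] = m1b; bm[3] = m2b;
      bse2[0] = se2a; bse2[1] = se2b;
    }
  }
  if (ncand == 0) return R_NilValue;

  const bool prom1 = bz1 >= bz2;
  IntegerVector side;                       // child-1 levels, 1-based codes
  if (ordinal) {
    side = IntegerVector(1, obs[best_c - 1] + 1);
  } else {
    std::vector<int> sv;
    for (int j = 0; j < ko - 1; ++j) {
      if (best_c & (1L << j)) sv.push_back(obs[j] + 1);
    }
    side = wrap(sv);
  }
  IntegerVector obs1(ko);
  for (int j = 0; j < ko; ++j) obs1[j] = obs[j] + 1;

  return List::create(
    _["p"] = best_p, _["ncand"] = ncand,
    _["z1"] = bz1, _["z2"] = bz2,
    _["promoted1"] = prom1,
    _["side"] = side, _["obs"] = obs1,
    _["n1"] = prom1 ? bn[0] : bn[2], _["n2"] = prom1 ? bn[1] : bn[3],
    _["m1"] = prom1 ? bm[0] : bm[2], _["m2"] = prom1 ? bm[1] : bm[3],
    _["se"] = std::sqrt(prom1 ? bse2[0] : bse2[1]),
    _["n_per_arm"] = NumericVector::create(bn[0], bn[1], bn[2], bn[3]));
}
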