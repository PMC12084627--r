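#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int>& par, int i) {
  while (par[i] != i) {
    par[i] = par[par[i]];
    i = par[i];
  }
  return i;
}

// Maximum absolute cluster mass of one t map (time fastest within channel).
// Suprathreshold runs per channel are merged across neighboring channels
// when their time intervals overlap (union-find over runs), separately for
// positive and negative excursions.
static double max_mass_one(const std::vector<double>& t, int nt, int nch,
                           double thr, const std::vector<std::vector<int>>& adj) {
  double best = 0.0;
  for (int sgn = 0; sgn < 2; ++sgn) {
    const double s = sgn ? -1.0 : 1.0;
    std::vector<int> rch, rt0, rt1;
    std::vector<double> rmass;
    for (int ch = 0; ch < nch; ++ch) {
      const int base = ch * nt;
      int i = 0;
      while (i < nt) {
        if (s * t[base + i] > thr) {
          int j = i;
          double m = 0.0;
          while (j < nt && s * t[base + j] > thr) {
            m += t[base + j];
            ++j;
          }
          rch.push_back(ch); rt0.push_back(i); rt1.push_back(j - 1);
          rmass.push_back(m);
          i = j;
        } else {
          ++i;
        }
      }
    }
    const int nr = (int)rch.size();
    if (nr == 0) continue;
    std::vector<int> first(nch, -1), last(nch, -1), par(nr);
    for (int i = 0; i < nr; ++i) {
      if (first[rch[i]] < 0) first[rch[i]] = i;
      last[rch[i]] = i;
      par[i] = i;
    }
    for (int c1 = 0; c1 < nch; ++c1) {
      if (first[c1] < 0) continue;
      for (int c2 : adj[c1]) {
        if (c2 <= c1 || first[c2] < 0) continue;
        int i = first[c1], j = first[c2];
        while (i <= last[c1] && j <= last[c2]) {
          if (rt1[i] < rt0[j]) ++i;
          else if (rt1[j] < rt0[i]) ++j;
          else {
            int ri = uf_find(par, i), rj = uf_find(par, j);
            if (ri != rj) par[ri] = rj;
            if (rt1[i] <= rt1[j]) ++i; else ++j;
          }
        }
      }
    }
    std::vector<double> agg(nr, 0.0);
    for (int i = 0; i < nr; ++i) agg[uf_find(par, i)] += rmass[i];
    for (int i = 0; i < nr; ++i) {
      const double a = std::fabs(agg[i]);
      if (a > best) best = a;
    }
  }
  return best;
}

//' Null distribution of the maximum cluster mass (internal)
//'
//' For each sign assignment (row of `S`), computes the paired t map of the
//' sign-flipped participant difference maps `D` and returns the maximum
//' absolute spatiotemporal cluster mass.
//'
//' @param D participants x points matrix of difference maps, points laid
//'   out time-fastest within channel
//' @param S assignments x participants matrix of +/-1 sign flips
//' @param thr cluster-forming t threshold
//' @param nt,nch number of time points and channels
//' @param adj list of integer neighbor vectors (1-based) per channel
//' @return numeric vector of max |cluster mass| per assignment
//' @keywords internal
// [[Rcpp::export]]
NumericVector cluster_null_stats(NumericMatrix D, NumericMatrix S,
                                 double thr, int nt, int nch, List adj) {
  const int n = D.nrow(), npts = D.ncol(), P = S.nrow();
  std::vector<std::vector<int>> adjv(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector nb = adj[c];
    for (int k = 0; k < nb.size(); ++k) adjv[c].push_back(nb[k] - 1);
  }
  std::vector<double> ssq(npts, 0.0);
  for (int i = 0; i < npts; ++i) {
    const double* col = &D(0, i);
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += col[j] * col[j];
    ssq[i] = acc;
  }
  const double tsc = std::sqrt((double)(n - 1) / (double)n);
  NumericVector out(P);
  std::vector<double> tmap(npts), srow(n);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < n; ++j) srow[j] = S(p, j);
    for (int i = 0; i < npts; ++i) {
      const double* col = &D(0, i);
      double m = 0.0;
      for (int j = 0; j < n; ++j) m += srow[j] * col[j];
      double v = ssq[i] - m * m / n;
      if (v < 1e-12) v = 1e-12;
      tmap[i] = m * tsc / std::sqrt(v);
    }
    out[p] = max_mass_one(tmap, nt, nch, thr, adjv);
  }
  return out;
}
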