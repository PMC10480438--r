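#include <Rcpp.h>
using namespace Rcpp;

// Mean per-frame Euclidean distance for every unordered dyad.
// x, y: frames x individuals, NA where an individual is not tracked.
// [[Rcpp::export(name = ".pair_mean_dist")]]
List pair_mean_dist(NumericMatrix x, NumericMatrix y) {
  const int nf = x.nrow(), n = x.ncol();
  const int nd = n * (n - 1) / 2;
  IntegerVector ia(nd), ib(nd), nov(nd);
  NumericVector dm(nd);
  // complete-track fast path: most tracks have no gaps
  std::vector<bool> has_na(n, false);
  for (int i = 0; i < n; ++i) {
    const double *xi = &x(0, i);
    for (int t = 0; t < nf; ++t) {
      if (ISNAN(xi[t])) { has_na[i] = true; break; }
    }
  }
  int k = 0;
  for (int i = 0; i < n; ++i) {
    const double *xi = &x(0, i), *yi = &y(0, i);
    for (int j = i + 1; j < n; ++j, ++k) {
      const double *xj = &x(0, j), *yj = &y(0, j);
      double s = 0.0;
      int c = 0;
      if (!has_na[i] && !has_na[j]) {
        for (int t = 0; t < nf; ++t) {
          const double dx = xi[t] - xj[t], dy = yi[t] - yj[t];
          s += sqrt(dx * dx + dy * dy);
        }
        c = nf;
      } else {
        for (int t = 0; t < nf; ++t) {
          if (ISNAN(xi[t]) || ISNAN(xj[t])) continue;
          const double dx = xi[t] - xj[t], dy = yi[t] - yj[t];
          s += sqrt(dx * dx + dy * dy);
          ++c;
        }
      }
      ia[k] = i + 1;
      ib[k] = j + 1;
      nov[k] = c;
      dm[k] = c > 0 ? s / c : NA_REAL;
    }
  }
  return List::create(_["i"] = ia, _["j"] = ib, _["d"] = dm, _["n"] = nov);
}

// Delayed directional correlation.
// hx, hy: frames x individuals unit-heading components, NA where invalid.
// taus: candidate delays in frames, already ordered by preference
// (smallest |tau| first, negative before positive); ties in the running
// maximum are resolved by strict ">" so the first-preferred delay wins.
// A delay competes only if it has at least min_overlap valid overlapping
// frames; both endpoints of each product must lie inside the session.
// [[Rcpp::export(name = ".dir_corr")]]
List dir_corr(NumericMatrix hx, NumericMatrix hy, IntegerVector taus,
              int min_overlap) {
  const int nf = hx.nrow(), n = hx.ncol(), nt = taus.size();
  const int nd = n * (n - 1) / 2;
  IntegerVector ia(nd), ib(nd), best(nd), n0(nd);
  NumericVector cmax(nd);
  LogicalVector has(nd);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      ia[k] = i + 1;
      ib[k] = j + 1;
      int overlap0 = 0;
      for (int t = 0; t < nf; ++t)
        if (!ISNAN(hx(t, i)) && !ISNAN(hx(t, j))) ++overlap0;
      bool found = false;
      double bestc = NA_REAL;
      int bestt = NA_INTEGER;
      for (int ti = 0; ti < nt; ++ti) {
        const int tau = taus[ti];
        const int lo = tau < 0 ? -tau : 0;
        const int hi = tau > 0 ? nf - tau : nf;
        double s = 0.0;
        int c = 0;
        for (int t = lo; t < hi; ++t) {
          const double a = hx(t, i), b = hx(t + tau, j);
          if (ISNAN(a) || ISNAN(b)) continue;
          s += a * b + hy(t, i) * hy(t + tau, j);
          ++c;
        }
        if (c >= min_overlap) {
          const double cc = s / c;
          if (!found || cc > bestc) {
            found = true;
            bestc = cc;
            bestt = tau;
          }
        }
      }
      n0[k] = overlap0;
      has[k] = found;
      cmax[k] = found ? bestc : NA_REAL;
      best[k] = found ? bestt : NA_INTEGER;
    }
  }
  return List::create(_["i"] = ia, _["j"] = ib, _["c"] = cmax,
                      _["tau"] = best, _["n0"] = n0, _["has"] = has);
}
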