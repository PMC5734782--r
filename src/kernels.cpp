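#include <Rcpp.h>
using namespace Rcpp;

// Lower-triangle Bray-Curtis dissimilarities between columns of x
// (taxa rows x sample columns). d_ij = sum|x_i - x_j| / sum(x_i + x_j).
// [[Rcpp::export(name = ".bray_curtis_lower")]]
NumericVector bray_curtis_lower(NumericMatrix x) {
  const int nt = x.nrow(), ns = x.ncol();
  NumericVector out((double) ns * (ns - 1) / 2);
  int idx = 0;
  for (int i = 0; i < ns - 1; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      double num = 0.0, den = 0.0;
      const double *xi = &x(0, i), *xj = &x(0, j);
      for (int k = 0; k < nt; ++k) {
        num += std::fabs(xi[k] - xj[k]);
        den += xi[k] + xj[k];
      }
      out[idx++] = (den > 0.0) ? num / den : NA_REAL;
    }
  }
  return out;
}

// Lower-triangle binary Jaccard: d = 1 - |A & B| / |A | B|, presence = x > 0.
// [[Rcpp::export(name = ".jaccard_binary_lower")]]
NumericVector jaccard_binary_lower(NumericMatrix x) {
  const int nt = x.nrow(), ns = x.ncol();
  NumericVector out((double) ns * (ns - 1) / 2);
  int idx = 0;
  for (int i = 0; i < ns - 1; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      int inter = 0, uni = 0;
      const double *xi = &x(0, i), *xj = &x(0, j);
      for (int k = 0; k < nt; ++k) {
        const bool a = xi[k] > 0.0, b = xj[k] > 0.0;
        if (a && b) ++inter;
        if (a || b) ++uni;
      }
      out[idx++] = (uni > 0) ? 1.0 - (double) inter / uni : NA_REAL;
    }
  }
  return out;
}

// Multivariate hypergeometric draw of `depth` reads per column, without
// replacement, via sequential conditional hypergeometrics.  Uses R's RNG so
// results are reproducible under set.seed().  Columns whose total is below
// `depth` are returned untouched; the caller decides whether to drop them.
// [[Rcpp::export(name = ".rarefy_matrix")]]
IntegerMatrix rarefy_matrix(IntegerMatrix x, int depth) {
  const int nt = x.nrow(), ns = x.ncol();
  IntegerMatrix out(nt, ns);
  RNGScope scope;
  for (int j = 0; j < ns; ++j) {
    double total = 0.0;
    for (int k = 0; k < nt; ++k) total += x(k, j);
    if (total < depth) {
      for (int k = 0; k < nt; ++k) out(k, j) = x(k, j);
      continue;
    }
    double remaining = total;
    int need = depth;
    for (int k = 0; k < nt && need > 0; ++k) {
      const int ck = x(k, j);
      if (ck == 0) { remaining -= 0; continue; }
      // draw from hypergeometric: `need` draws from ck white, remaining-ck black
      int take = (remaining - ck < 0.5)
        ? need
        : (int) ::Rf_rhyper((double) ck, remaining - ck, (double) need);
      out(k, j) = take;
      need -= take;
      remaining -= ck;
    }
  }
  return out;
}
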