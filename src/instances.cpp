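#include <Rcpp.h>
using namespace Rcpp;

// Minimal-span instance search over packed promoter profiles.
//
// Packed layout: all sites of all promoters concatenated, sorted by
// start within each promoter. promo_off is a (P+1)-vector of 0-based
// offsets delimiting each promoter's slice; promo_gene maps each
// promoter to its 1-based gene index.
//
// An instance of an element sequence e1..eM on a promoter is a
// selection of distinct sites matching the oriented keys in order,
// strictly non-overlapping (next.start > prev.end). For a fixed first
// site, greedily taking at each later element the feasible site with
// the smallest end minimizes the last end (the downstream constraint
// depends only on the running end), hence the span for that first
// site; the promoter minimum is the minimum over first sites.

static double promoter_min_span(const int* start, const int* end,
                                const int* key, int lo, int hi,
                                const int* elems, int m) {
  double best = NA_REAL;
  for (int i = lo; i < hi; ++i) {
    if (key[i] != elems[0]) continue;
    int bound = end[i];
    bool ok = true;
    for (int e = 1; e < m; ++e) {
      int best_end = NA_INTEGER;
      bool found = false;
      for (int j = lo; j < hi; ++j) {
        if (key[j] != elems[e]) continue;
        if (start[j] <= bound) continue;
        if (!found || end[j] < best_end) { best_end = end[j]; found = true; }
      }
      if (!found) { ok = false; break; }
      bound = best_end;
    }
    if (ok) {
      double span = (double)bound - (double)start[i] + 1.0;
      if (ISNA(best) || span < best) best = span;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_min_spans(IntegerVector site_start, IntegerVector site_end,
                            IntegerVector site_key, IntegerVector promo_off,
                            IntegerVector promo_gene, int n_genes,
                            IntegerVector elems) {
  int P = promo_off.size() - 1;
  int m = elems.size();
  NumericVector out(n_genes, NA_REAL);
  const int* start = INTEGER(site_start);
  const int* end = INTEGER(site_end);
  const int* key = INTEGER(site_key);
  const int* el = INTEGER(elems);
  for (int p = 0; p < P; ++p) {
    int lo = promo_off[p], hi = promo_off[p + 1];
    if (hi - lo < m) continue;
    double s = promoter_min_span(start, end, key, lo, hi, el, m);
    if (!ISNA(s)) {
      int g = promo_gene[p] - 1;
      if (ISNA(out[g]) || s < out[g]) out[g] = s;
    }
  }
  return out;
}

// Gene x key presence matrix (heuristic gene-level presence: a key is
// present for a gene if any of its promoters carries a matching site).
// [[Rcpp::export]]
LogicalMatrix cpp_key_gene_presence(IntegerVector site_key,
                                    IntegerVector promo_off,
                                    IntegerVector promo_gene,
                                    int n_genes, int n_keys) {
  int P = promo_off.size() - 1;
  LogicalMatrix out(n_genes, n_keys);
  for (int p = 0; p < P; ++p) {
    int g = promo_gene[p] - 1;
    for (int j = promo_off[p]; j < promo_off[p + 1]; ++j) {
      out(g, site_key[j] - 1) = true;
    }
  }
  return out;
}
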