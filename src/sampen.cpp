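#include <Rcpp.h>
using namespace Rcpp;

// Sample-entropy template match counts over discontinuous segments.
// x: concatenated samples; seg_id: integer segment label per sample
// (templates never span a segment boundary; matched PAIRS may come from
// different segments — that is the point of pooling across trials).
// Valid template starts are those with m+1 samples available inside their
// segment, so that A (length m+1 matches) and B (length m matches) are
// counted over the same template set and A/B is a conditional probability.
// Match criterion: Chebyshev distance <= r.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, IntegerVector seg_id,
                                int m, double r) {
    int n = x.size();
    std::vector<int> starts;
    starts.reserve(n);
    for (int i = 0; i + m < n; ++i) {
        bool ok = true;
        for (int k = 1; k <= m; ++k)
            if (seg_id[i + k] != seg_id[i]) { ok = false; break; }
        if (ok && seg_id[i + m] == seg_id[i]) starts.push_back(i);
    }
    double A = 0.0, B = 0.0;
    int ns = (int) starts.size();
    const double *xp = REAL(x);
    for (int p = 0; p < ns; ++p) {
        const double *u = xp + starts[p];
        for (int q = p + 1; q < ns; ++q) {
            const double *v = xp + starts[q];
            bool bmatch = true;
            for (int k = 0; k < m; ++k) {
                if (std::abs(u[k] - v[k]) > r) { bmatch = false; break; }
            }
            if (!bmatch) continue;
            B += 1.0;
            if (std::abs(u[m] - v[m]) <= r) A += 1.0;
        }
    }
    return NumericVector::create(_["A"] = A, _["B"] = B,
                                 _["n_templates"] = (double) ns);
}
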