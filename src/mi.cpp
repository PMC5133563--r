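#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in mutual information (nats) from joint counts of two integer label
// vectors with values in 0..(kx-1) and 0..(ky-1).
static double mi_from_codes(const int* x, const int* y, int n, int kx, int ky) {
    std::vector<double> joint((size_t)kx * ky, 0.0);
    std::vector<double> px(kx, 0.0), py(ky, 0.0);
    for (int i = 0; i < n; ++i) {
        joint[(size_t)x[i] * ky + y[i]] += 1.0;
        px[x[i]] += 1.0;
        py[y[i]] += 1.0;
    }
    double mi = 0.0, dn = (double)n;
    for (int a = 0; a < kx; ++a) {
        if (px[a] == 0.0) continue;
        for (int b = 0; b < ky; ++b) {
            double c = joint[(size_t)a * ky + b];
            if (c > 0.0)
                mi += (c / dn) * std::log(c * dn / (px[a] * py[b]));
        }
    }
    return mi > 0.0 ? mi : 0.0; // clamp tiny negative rounding error
}

// [[Rcpp::export]]
double cpp_mi(IntegerVector x, IntegerVector y, int kx, int ky) {
    if (x.size() != y.size()) stop("length mismatch");
    return mi_from_codes(INTEGER(x), INTEGER(y), x.size(), kx, ky);
}

// MI of every column of X against the target vector y.
// [[Rcpp::export]]
NumericVector cpp_mi_profile(IntegerMatrix X, IntegerVector y,
                             IntegerVector kx, int ky) {
    int n = X.nrow(), p = X.ncol();
    if (y.size() != n) stop("length mismatch");
    NumericVector out(p);
    for (int j = 0; j < p; ++j)
        out[j] = mi_from_codes(&X(0, j), INTEGER(y), n, kx[j], ky);
    return out;
}
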