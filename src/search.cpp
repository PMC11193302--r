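#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive Pearson-correlation scans over two- and three-band index forms.
// R is samples x bands (column-major: one band = one contiguous column).
// Correlations use pairwise deletion: samples with a degenerate denominator
// (|den| < eps) or non-finite values are skipped per combination; a
// combination with fewer than min_valid contributing samples is invalid.
//
// The running best is replaced only when |r| exceeds it by more than
// TIE_EPS, so combinations whose |r| agree to floating-point noise resolve
// to the lexicographically smallest wavelength tuple (the scan order).

static const double TIE_EPS = 1e-12;

// two-band forms: 0 = RVI, 1 = NDVI, 2 = DVI
static inline double index2(int form, double r1, double r2, bool &ok, double eps) {
    switch (form) {
    case 0:
        if (std::fabs(r2) < eps) { ok = false; return 0.0; }
        return r1 / r2;
    case 1: {
        double den = r1 + r2;
        if (std::fabs(den) < eps) { ok = false; return 0.0; }
        return (r1 - r2) / den;
    }
    default:
        return r1 - r2;
    }
}

// three-band forms: 0..6 = 3BI-1 .. 3BI-7
static inline double index3(int form, double r1, double r2, double r3,
                            bool &ok, double eps) {
    double num, den;
    switch (form) {
    case 0: num = r1; den = r2 * r3; break;
    case 1: num = r1; den = r2 + r3; break;
    case 2: num = r1 - r2; den = r2 + r3; break;
    case 3: num = r1 - r2; den = r2 - r3; break;
    case 4: num = r2 + r3; den = r1; break;
    case 5: num = r1 - r2; den = (r1 - r2) - (r2 - r3); break;
    default: return (r1 - r2) - (r2 - r3);
    }
    if (std::fabs(den) < eps) { ok = false; return 0.0; }
    return num / den;
}

struct RunningCorr {
    int n = 0;
    double sx = 0.0, sy = 0.0, sxx = 0.0, syy = 0.0, sxy = 0.0;
    inline void add(double x, double y) {
        ++n;
        sx += x; sy += y;
        sxx += x * x; syy += y * y; sxy += x * y;
    }
    // NaN when undefined (too few points or zero variance)
    inline double r(int min_valid) const {
        if (n < min_valid) return NA_REAL;
        double vx = n * sxx - sx * sx;
        double vy = n * syy - sy * sy;
        if (vx <= 0.0 || vy <= 0.0) return NA_REAL;
        return (n * sxy - sx * sy) / std::sqrt(vx * vy);
    }
};

// [[Rcpp::export]]
List cpp_search_2d(NumericMatrix R, NumericVector y,
                   IntegerVector idx1, IntegerVector idx2,
                   NumericVector wl1, NumericVector wl2,
                   int form, double eps, int min_valid, bool keep_map) {
    const int ns = R.nrow();
    const int n1 = idx1.size(), n2 = idx2.size();
    NumericMatrix map_r, map_n;
    if (keep_map) {
        map_r = NumericMatrix(n1, n2);
        map_n = NumericMatrix(n1, n2);
        std::fill(map_r.begin(), map_r.end(), NA_REAL);
        std::fill(map_n.begin(), map_n.end(), NA_REAL);
    }
    double best_r = NA_REAL;
    int best_i = -1, best_j = -1, best_n = 0;
    for (int i = 0; i < n1; ++i) {
        const double *c1 = &R(0, idx1[i] - 1);
        for (int j = 0; j < n2; ++j) {
            if (wl1[i] == wl2[j]) continue;
            const double *c2 = &R(0, idx2[j] - 1);
            RunningCorr rc;
            for (int s = 0; s < ns; ++s) {
                double r1 = c1[s], r2 = c2[s];
                if (!R_finite(r1) || !R_finite(r2)) continue;
                bool ok = true;
                double v = index2(form, r1, r2, ok, eps);
                if (!ok || !R_finite(v)) continue;
                rc.add(v, y[s]);
            }
            double r = rc.r(min_valid);
            if (keep_map) {
                map_r(i, j) = r;
                map_n(i, j) = rc.n;
            }
            if (R_finite(r) &&
                (!R_finite(best_r) || std::fabs(r) > std::fabs(best_r) + TIE_EPS)) {
                best_r = r; best_i = i; best_j = j; best_n = rc.n;
            }
        }
    }
    List out = List::create(
        _["best_i"] = best_i + 1, _["best_j"] = best_j + 1,
        _["best_r"] = best_r, _["best_n"] = best_n);
    if (keep_map) { out["map_r"] = map_r; out["map_n"] = map_n; }
    return out;
}

// [[Rcpp::export]]
List cpp_search_3d(NumericMatrix R, NumericVector y,
                   IntegerVector idx1, IntegerVector idx2, IntegerVector idx3,
                   NumericVector wl1, NumericVector wl2, NumericVector wl3,
                   int form, double eps, int min_valid, bool keep_map) {
    const int ns = R.nrow();
    const int n1 = idx1.size(), n2 = idx2.size(), n3 = idx3.size();
    std::vector<double> map_r, map_n;
    if (keep_map) {
        double total = (double)n1 * n2 * n3;
        if (total > 2e7) stop("3-D map too large to store; use keep_map = FALSE");
        map_r.assign((size_t)total, NA_REAL);
        map_n.assign((size_t)total, NA_REAL);
    }
    double best_r = NA_REAL;
    int best_i = -1, best_j = -1, best_k = -1, best_n = 0;
    for (int i = 0; i < n1; ++i) {
        const double *c1 = &R(0, idx1[i] - 1);
        for (int j = 0; j < n2; ++j) {
            if (wl1[i] == wl2[j]) continue;
            const double *c2 = &R(0, idx2[j] - 1);
            for (int k = 0; k < n3; ++k) {
                if (wl1[i] == wl3[k] || wl2[j] == wl3[k]) continue;
                const double *c3 = &R(0, idx3[k] - 1);
                RunningCorr rc;
                for (int s = 0; s < ns; ++s) {
                    double r1 = c1[s], r2 = c2[s], r3 = c3[s];
                    if (!R_finite(r1) || !R_finite(r2) || !R_finite(r3)) continue;
                    bool ok = true;
                    double v = index3(form, r1, r2, r3, ok, eps);
                    if (!ok || !R_finite(v)) continue;
                    rc.add(v, y[s]);
                }
                double r = rc.r(min_valid);
                if (keep_map) {
                    size_t pos = (size_t)i + (size_t)n1 * ((size_t)j + (size_t)n2 * k);
                    map_r[pos] = r;
                    map_n[pos] = rc.n;
                }
                if (R_finite(r) &&
                    (!R_finite(best_r) ||
                     std::fabs(r) > std::fabs(best_r) + TIE_EPS)) {
                    best_r = r; best_i = i; best_j = j; best_k = k; best_n = rc.n;
                }
            }
        }
        Rcpp::checkUserInterrupt();
    }
    List out = List::create(
        _["best_i"] = best_i + 1, _["best_j"] = best_j + 1, _["best_k"] = best_k + 1,
        _["best_r"] = best_r, _["best_n"] = best_n);
    if (keep_map) {
        out["map_r"] = NumericVector(map_r.begin(), map_r.end());
        out["map_n"] = NumericVector(map_n.begin(), map_n.end());
    }
    return out;
}
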