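#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// |mean(b) - mean(a)| / sqrt(var(a) + var(b)) * n  over x[0..na) vs x[na..na+nb)
static double u_unpaired(const std::vector<double>& x, int na, int nb) {
    double sa = 0, sa2 = 0, sb = 0, sb2 = 0;
    for (int i = 0; i < na; ++i) { sa += x[i]; sa2 += x[i] * x[i]; }
    for (int i = na; i < na + nb; ++i) { sb += x[i]; sb2 += x[i] * x[i]; }
    double ma = sa / na, mb = sb / nb;
    double va = na > 1 ? (sa2 - na * ma * ma) / (na - 1) : 0.0;
    double vb = nb > 1 ? (sb2 - nb * mb * mb) / (nb - 1) : 0.0;
    if (va < 0) va = 0;
    if (vb < 0) vb = 0;
    double num = std::fabs(mb - ma), den = std::sqrt(va + vb);
    if (den == 0) return num == 0 ? 0.0 : R_PosInf;
    return num / den * (na + nb);
}

// |mean(d)| / sd(d) * n
static double u_paired(const std::vector<double>& d) {
    int n = (int) d.size();
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += d[i]; s2 += d[i] * d[i]; }
    double m = s / n;
    double v = n > 1 ? (s2 - n * m * m) / (n - 1) : 0.0;
    if (v < 0) v = 0;
    double num = std::fabs(m), den = std::sqrt(v);
    if (den == 0) return num == 0 ? 0.0 : R_PosInf;
    return num / den * n;
}

// exceedance count with ties counted as exceeding; infinities compare equal
static inline bool exceeds(double ur, double uobs) {
    if (!std::isfinite(uobs)) return !std::isfinite(ur);
    return ur >= uobs;
}

// Monte-Carlo permutation p-values, unpaired: for each feature (row), pool the
// observed values of both groups and re-partition them nRand times into the
// observed group sizes. p = (#{u_r >= u_obs} + 1) / (nRand + 1). Uses R's RNG.
// [[Rcpp::export(name = ".permNullUnpaired")]]
NumericVector permNullUnpaired(NumericMatrix A, NumericMatrix B, int nRand) {
    int nFeat = A.nrow();
    NumericVector p(nFeat);
    std::vector<double> pool;
    for (int f = 0; f < nFeat; ++f) {
        pool.clear();
        int na = 0, nb = 0;
        for (int j = 0; j < A.ncol(); ++j)
            if (!NumericMatrix::is_na(A(f, j))) { pool.push_back(A(f, j)); ++na; }
        for (int j = 0; j < B.ncol(); ++j)
            if (!NumericMatrix::is_na(B(f, j))) { pool.push_back(B(f, j)); ++nb; }
        if (na < 1 || nb < 1) { p[f] = 1.0; continue; }
        double uobs = u_unpaired(pool, na, nb);
        int count = 0;
        int n = na + nb;
        for (int r = 0; r < nRand; ++r) {
            // Fisher-Yates shuffle
            for (int i = n - 1; i > 0; --i) {
                int j = (int) (unif_rand() * (i + 1));
                if (j > i) j = i;
                std::swap(pool[i], pool[j]);
            }
            if (exceeds(u_unpaired(pool, na, nb), uobs)) ++count;
        }
        p[f] = (count + 1.0) / (nRand + 1.0);
    }
    return p;
}

// Monte-Carlo permutation p-values, paired: per feature, random sign flips of
// the complete-pair differences D (rows = features).
// [[Rcpp::export(name = ".permNullPaired")]]
NumericVector permNullPaired(NumericMatrix D, int nRand) {
    int nFeat = D.nrow();
    NumericVector p(nFeat);
    std::vector<double> d, ds;
    for (int f = 0; f < nFeat; ++f) {
        d.clear();
        for (int j = 0; j < D.ncol(); ++j)
            if (!NumericMatrix::is_na(D(f, j))) d.push_back(D(f, j));
        if (d.size() < 1) { p[f] = 1.0; continue; }
        double uobs = u_paired(d);
        ds = d;
        int count = 0;
        for (int r = 0; r < nRand; ++r) {
            for (size_t i = 0; i < d.size(); ++i)
                ds[i] = unif_rand() < 0.5 ? d[i] : -d[i];
            if (exceeds(u_paired(ds), uobs)) ++count;
        }
        p[f] = (count + 1.0) / (nRand + 1.0);
    }
    return p;
}
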