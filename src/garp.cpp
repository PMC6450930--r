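#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Core revealed-preference machinery on the cost-ratio matrix
//   W[i][j] = (p^i . x^j) / (p^i . x^i)
// At efficiency level e, bundle i is directly revealed preferred to j
// (R0) iff W[i][j] <= e, and strictly so (P0) iff W[i][j] < e.

// Minimax ("bottleneck") path closure: B[i][j] = min over nonempty
// directed paths i -> j of the maximum edge weight along the path.
// Floyd-Warshall recursion; row-major storage.
static void minimax_closure(std::vector<double> &B, int n) {
    for (int k = 0; k < n; ++k) {
        const double *rowk = &B[(size_t)k * n];
        for (int i = 0; i < n; ++i) {
            double bik = B[(size_t)i * n + k];
            double *rowi = &B[(size_t)i * n];
            // branchless min/max so the loop vectorizes
            for (int j = 0; j < n; ++j)
                rowi[j] = std::min(rowi[j], std::max(bik, rowk[j]));
        }
    }
}

static std::vector<double> as_rowmajor(const NumericMatrix &W) {
    int n = W.nrow();
    std::vector<double> B((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            B[(size_t)i * n + j] = W(i, j);
    return B;
}

// Supremal efficiency e* at which e-adjusted GARP still holds:
// a pair (i, j) is violated for e beyond max(B[i][j], W[j][i]), so
// e* = min over ordered pairs of that threshold, capped at 1.
static double estar_from(const std::vector<double> &B,
                         const std::vector<double> &W, int n) {
    double e = 1.0;
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            double t = std::max(B[(size_t)i * n + j], W[(size_t)j * n + i]);
            if (t < e) e = t;
        }
    }
    return e;
}

// [[Rcpp::export]]
NumericMatrix cpp_minimax_closure(NumericMatrix W) {
    int n = W.nrow();
    std::vector<double> B = as_rowmajor(W);
    minimax_closure(B, n);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            out(i, j) = B[(size_t)i * n + j];
    return out;
}

// [[Rcpp::export]]
double cpp_afriat_estar(NumericMatrix W) {
    int n = W.nrow();
    std::vector<double> Wr = as_rowmajor(W);
    std::vector<double> B(Wr);
    minimax_closure(B, n);
    return estar_from(B, Wr, n);
}

// Single-precision closure for the leave-one-out inner loop.  The cost
// ratios carry ~1e-7 relative float error, far below the 1e-4 reporting
// tolerance, and min/max recursions preserve the submatrix monotonicity
// (e*_{-i} >= e*) exactly because they never create new values.
static void minimax_closure_f(std::vector<float> &B, int n) {
    for (int k = 0; k < n; ++k) {
        const float *rowk = &B[(size_t)k * n];
        for (int i = 0; i < n; ++i) {
            float bik = B[(size_t)i * n + k];
            float *rowi = &B[(size_t)i * n];
            for (int j = 0; j < n; ++j)
                rowi[j] = std::min(rowi[j], std::max(bik, rowk[j]));
        }
    }
}

static double estar_from_f(const std::vector<float> &B,
                           const std::vector<float> &W, int n) {
    float e = 1.0f;
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            float t = std::max(B[(size_t)i * n + j], W[(size_t)j * n + i]);
            if (t < e) e = t;
        }
    }
    return (double)e;
}

// Leave-one-out e* series: e* of the full data and of each D_{-i}.
// [[Rcpp::export]]
List cpp_loo_estar(NumericMatrix W) {
    int n = W.nrow();
    std::vector<float> Wr((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            Wr[(size_t)i * n + j] = (float)W(i, j);
    std::vector<float> B(Wr);
    minimax_closure_f(B, n);
    double efull = estar_from_f(B, Wr, n);

    NumericVector eloo(n);
    int m = n - 1;
    std::vector<float> Wsub((size_t)m * m), Bsub((size_t)m * m);
    for (int drop = 0; drop < n; ++drop) {
        int ii = 0;
        for (int i = 0; i < n; ++i) {
            if (i == drop) continue;
            int jj = 0;
            for (int j = 0; j < n; ++j) {
                if (j == drop) continue;
                Wsub[(size_t)ii * m + jj] = Wr[(size_t)i * n + j];
                ++jj;
            }
            ++ii;
        }
        Bsub = Wsub;
        minimax_closure_f(Bsub, m);
        eloo[drop] = estar_from_f(Bsub, Wsub, m);
    }
    return List::create(_["e_full"] = efull, _["e_loo"] = eloo);
}

// Boolean reachability closure of the level-e relation R0.
static void reach_closure(std::vector<unsigned char> &A, int n) {
    for (int k = 0; k < n; ++k) {
        const unsigned char *rowk = &A[(size_t)k * n];
        for (int i = 0; i < n; ++i) {
            if (!A[(size_t)i * n + k]) continue;
            unsigned char *rowi = &A[(size_t)i * n];
            for (int j = 0; j < n; ++j)
                if (rowk[j]) rowi[j] = 1;
        }
    }
}

static std::vector<unsigned char> level_relation(const NumericMatrix &W,
                                                 double e) {
    int n = W.nrow();
    std::vector<unsigned char> A((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            A[(size_t)i * n + j] = (W(i, j) <= e) ? 1 : 0;
    return A;
}

// Ordered violating pairs (i, j): x^i R x^j and x^j P0 x^i at level e.
// [[Rcpp::export]]
IntegerMatrix cpp_garp_violation_pairs(NumericMatrix W, double e) {
    int n = W.nrow();
    std::vector<unsigned char> A = level_relation(W, e);
    reach_closure(A, n);
    std::vector<int> vi, vj;
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            if (A[(size_t)i * n + j] && W(j, i) < e) {
                vi.push_back(i + 1);
                vj.push_back(j + 1);
            }
        }
    }
    IntegerMatrix out(vi.size(), 2);
    for (size_t k = 0; k < vi.size(); ++k) {
        out(k, 0) = vi[k];
        out(k, 1) = vj[k];
    }
    return out;
}

// [[Rcpp::export]]
bool cpp_garp_satisfied(NumericMatrix W, double e) {
    int n = W.nrow();
    std::vector<unsigned char> A = level_relation(W, e);
    reach_closure(A, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            if (A[(size_t)i * n + j] && W(j, i) < e) return false;
        }
    return true;
}
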