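#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// Bounded-variable primal revised simplex for LPs of the form
//
//   maximize  c'x   subject to   A x = 0,   0 <= x <= u   (u finite)
//
// which is the shape of every steady-state flux program in this package:
// the all-zero flux vector is always feasible, so no phase-1 is needed.
// The basis starts as m artificial columns fixed at [0,0]; they may leave
// the basis but are never priced back in. Dantzig pricing with a permanent
// switch to Bland's rule after a long degenerate stall guarantees
// termination. The basis inverse is maintained by eta updates and
// refactorized periodically (and before extracting the final solution).

static const double PIV_TOL = 1e-9;    // minimum pivot magnitude
static const double RATIO_EPS = 1e-9;  // tie tolerance in the ratio test

// Gauss-Jordan inverse with partial pivoting; returns false if singular.
static bool invert_dense(std::vector<double> B, int m, std::vector<double>& Binv)
{
    Binv.assign((size_t)m * m, 0.0);
    for (int i = 0; i < m; ++i) Binv[(size_t)i * m + i] = 1.0;
    for (int k = 0; k < m; ++k) {
        int piv = k;
        double best = std::fabs(B[(size_t)k * m + k]);
        for (int i = k + 1; i < m; ++i) {
            double v = std::fabs(B[(size_t)i * m + k]);
            if (v > best) { best = v; piv = i; }
        }
        if (best < 1e-12) return false;
        if (piv != k) {
            for (int j = 0; j < m; ++j) {
                std::swap(B[(size_t)piv * m + j], B[(size_t)k * m + j]);
                std::swap(Binv[(size_t)piv * m + j], Binv[(size_t)k * m + j]);
            }
        }
        double d = B[(size_t)k * m + k];
        for (int j = 0; j < m; ++j) { B[(size_t)k * m + j] /= d; Binv[(size_t)k * m + j] /= d; }
        for (int i = 0; i < m; ++i) {
            if (i == k) continue;
            double f = B[(size_t)i * m + k];
            if (f == 0.0) continue;
            for (int j = 0; j < m; ++j) {
                B[(size_t)i * m + j]    -= f * B[(size_t)k * m + j];
                Binv[(size_t)i * m + j] -= f * Binv[(size_t)k * m + j];
            }
        }
    }
    return true;
}

// [[Rcpp::export]]
List simplex_bounded(int m, int n,
                     IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                     NumericVector obj, NumericVector ub,
                     double tol = 1e-9, int maxit = 100000)
{
    // variable j in [0,n): structural; j in [n, n+m): artificial (bounds [0,0])
    std::vector<int> basis(m);
    std::vector<signed char> vstat((size_t)n + m); // 0 at lower, 1 at upper, 2 basic
    std::vector<double> Binv((size_t)m * m, 0.0), xB(m, 0.0), cB(m, 0.0), ubB(m, 0.0);
    std::vector<double> y(m), w(m);

    for (int i = 0; i < m; ++i) {
        basis[i] = n + i;
        Binv[(size_t)i * m + i] = 1.0;
        vstat[(size_t)n + i] = 2;
    }
    for (int j = 0; j < n; ++j) vstat[j] = 0;

    bool bland = false;
    int degen_run = 0, iter = 0, status = 1; // 1 = iteration limit unless proven optimal

    // refactorize: rebuild Binv from the current basis and recompute xB
    auto refactor = [&](void) -> bool {
        std::vector<double> B((size_t)m * m, 0.0);
        for (int i = 0; i < m; ++i) {
            int j = basis[i];
            if (j >= n) {
                B[(size_t)(j - n) * m + i] = 1.0;
            } else {
                for (int k = Ap[j]; k < Ap[j + 1]; ++k)
                    B[(size_t)Ai[k] * m + i] = Ax[k];
            }
        }
        std::vector<double> Bi;
        if (!invert_dense(B, m, Bi)) return false;
        Binv.swap(Bi);
        // rhs = -sum_{j nonbasic at upper} a_j * u_j  (b itself is 0)
        std::vector<double> rhs(m, 0.0);
        for (int j = 0; j < n; ++j) {
            if (vstat[j] != 1) continue;
            double uj = ub[j];
            if (uj == 0.0) continue;
            for (int k = Ap[j]; k < Ap[j + 1]; ++k) rhs[Ai[k]] -= Ax[k] * uj;
        }
        for (int i = 0; i < m; ++i) {
            double s = 0.0;
            for (int k = 0; k < m; ++k) s += Binv[(size_t)i * m + k] * rhs[k];
            xB[i] = (std::fabs(s) < 1e-11) ? 0.0 : s;
        }
        return true;
    };

    for (iter = 0; iter < maxit; ++iter) {
        // y = cB' Binv
        for (int k = 0; k < m; ++k) {
            double s = 0.0;
            for (int i = 0; i < m; ++i) s += cB[i] * Binv[(size_t)i * m + k];
            y[k] = s;
        }
        // pricing over structural nonbasic columns
        int jin = -1, dirin = 0;
        double bestimp = tol;
        for (int j = 0; j < n; ++j) {
            if (vstat[j] == 2) continue;
            double d = obj[j];
            for (int k = Ap[j]; k < Ap[j + 1]; ++k) d -= y[Ai[k]] * Ax[k];
            double imp;
            int dir;
            if (vstat[j] == 0 && d > tol) { imp = d; dir = +1; }
            else if (vstat[j] == 1 && d < -tol) { imp = -d; dir = -1; }
            else continue;
            if (bland) { jin = j; dirin = dir; break; }
            if (imp > bestimp) { bestimp = imp; jin = j; dirin = dir; }
        }
        if (jin < 0) { status = 0; break; } // optimal

        // w = Binv * a_jin
        std::fill(w.begin(), w.end(), 0.0);
        for (int k = Ap[jin]; k < Ap[jin + 1]; ++k) {
            double v = Ax[k]; int r = Ai[k];
            for (int i = 0; i < m; ++i) w[i] += Binv[(size_t)i * m + r] * v;
        }

        // ratio test: entering moves by t (dir +1 from lower, -1 from upper);
        // basics change by -t*dir*w
        double tmin = ub[jin]; // bound-to-bound flip distance
        for (int i = 0; i < m; ++i) {
            double d = dirin * w[i];
            if (d > PIV_TOL) {
                double ti = xB[i] / d;
                if (ti < tmin) tmin = ti;
            } else if (d < -PIV_TOL) {
                double ti = (ubB[i] - xB[i]) / (-d);
                if (ti < tmin) tmin = ti;
            }
        }
        if (tmin < 0) tmin = 0;

        // choose leaving row among blockers at tmin
        int rlv = -1;
        double bestpiv = 0.0;
        for (int i = 0; i < m; ++i) {
            double d = dirin * w[i];
            double ti;
            if (d > PIV_TOL) ti = xB[i] / d;
            else if (d < -PIV_TOL) ti = (ubB[i] - xB[i]) / (-d);
            else continue;
            if (ti <= tmin + RATIO_EPS) {
                if (bland) {
                    if (rlv < 0 || basis[i] < basis[rlv]) rlv = i;
                } else if (std::fabs(d) > bestpiv) {
                    bestpiv = std::fabs(d); rlv = i;
                }
            }
        }

        if (rlv < 0 || ub[jin] <= tmin + RATIO_EPS) {
            // bound flip of the entering variable, no basis change
            double t = ub[jin];
            for (int i = 0; i < m; ++i) {
                xB[i] -= t * dirin * w[i];
                if (xB[i] < 0 && xB[i] > -1e-9) xB[i] = 0.0;
            }
            vstat[jin] = (vstat[jin] == 0) ? 1 : 0;
            degen_run = 0;
            continue;
        }

        // pivot
        double t = tmin;
        for (int i = 0; i < m; ++i) {
            xB[i] -= t * dirin * w[i];
            if (xB[i] < 0 && xB[i] > -1e-9) xB[i] = 0.0;
        }
        int jout = basis[rlv];
        vstat[jout] = (dirin * w[rlv] > 0) ? 0 : 1; // hit lower : upper
        basis[rlv] = jin;
        vstat[jin] = 2;
        xB[rlv] = (dirin > 0) ? t : ub[jin] - t;
        cB[rlv]  = obj[jin];
        ubB[rlv] = ub[jin];

        double piv = w[rlv];
        double* rowr = &Binv[(size_t)rlv * m];
        for (int k = 0; k < m; ++k) rowr[k] /= piv;
        for (int i = 0; i < m; ++i) {
            if (i == rlv) continue;
            double f = w[i];
            if (f == 0.0) continue;
            double* rowi = &Binv[(size_t)i * m];
            for (int k = 0; k < m; ++k) rowi[k] -= f * rowr[k];
        }

        if (t < 1e-10) {
            if (++degen_run > 1000) bland = true;
        } else degen_run = 0;

        if ((iter + 1) % 500 == 0) refactor();
    }

    refactor(); // clean solution before extraction

    NumericVector x(n);
    for (int j = 0; j < n; ++j)
        x[j] = (vstat[j] == 1) ? ub[j] : 0.0;
    for (int i = 0; i < m; ++i)
        if (basis[i] < n) x[basis[i]] = xB[i];
    double z = 0.0;
    for (int j = 0; j < n; ++j) z += obj[j] * x[j];

    return List::create(_["x"] = x, _["objective"] = z,
                        _["status"] = status, _["iterations"] = iter);
}
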