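#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimal IkBa-NFkB negative feedback module.
// State y = (m, I, Nn, C):
//   m  : IkBa mRNA
//   I  : free cytoplasmic IkBa
//   Nn : free nuclear NFkB (the reported activity)
//   C  : cytoplasmic NFkB:IkBa complex
// Free cytoplasmic NFkB is the conserved remainder Nc = tot - Nn - C, so the
// total NFkB pool is conserved exactly by construction.
//
// Parameter vector layout (must match .core_param_order on the R side):
//  0 tot_nfkb        total NFkB abundance (a.u.)
//  1 ikk_gain        scales IKK activity (basal + stimulus input)
//  2 ikk_basal       basal IKK activity (fraction)
//  3 txn_basal       constitutive IkBa mRNA transcription (a.u./min)
//  4 txn_induced     NFkB-induced transcription Vmax (a.u./min)
//  5 txn_khalf       Hill half-saturation of induced transcription (a.u.)
//  6 mrna_decay      IkBa mRNA decay (1/min)
//  7 translation     IkBa translation (1/min)
//  8 deg_free_basal  basal degradation of free IkBa (1/min)
//  9 deg_free_ikk    IKK-dependent degradation of free IkBa (1/min per IKK)
// 10 deg_bound_basal basal degradation of complexed IkBa (1/min)
// 11 deg_bound_ikk   IKK-dependent degradation of complexed IkBa (1/min per IKK)
// 12 assoc           cytoplasmic NFkB + IkBa association (1/(a.u. min))
// 13 nuc_export      IkBa-mediated export of nuclear NFkB (1/(a.u. min))
// 14 nuc_import      nuclear import of free cytoplasmic NFkB (1/min)

static inline void rhs(const double *y, double *dy, const double *p, double u) {
    double m = y[0], I = y[1], Nn = y[2], C = y[3];
    double Nc = p[0] - Nn - C;
    if (Nc < 0.0) Nc = 0.0;
    double ikk = p[1] * (p[2] + u);
    if (ikk < 0.0) ikk = 0.0;
    double hill = (Nn * Nn) / (p[5] * p[5] + Nn * Nn);
    dy[0] = p[3] + p[4] * hill - p[6] * m;
    dy[1] = p[7] * m - (p[8] + p[9] * ikk) * I - p[12] * I * Nc - p[13] * I * Nn;
    dy[2] = p[14] * Nc - p[13] * I * Nn;
    dy[3] = p[12] * I * Nc + p[13] * I * Nn - (p[10] + p[11] * ikk) * C;
}

static inline void rk4_step(double *y, const double *p, double u0, double u1,
                            double h) {
    double k1[4], k2[4], k3[4], k4[4], yt[4];
    double um = 0.5 * (u0 + u1);
    rhs(y, k1, p, u0);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
    rhs(yt, k2, p, um);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
    rhs(yt, k3, p, um);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * k3[i];
    rhs(yt, k4, p, u1);
    for (int i = 0; i < 4; ++i) {
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (y[i] < 0.0) y[i] = 0.0;  // clip round-off undershoot
    }
}

// Phase 1: relax to steady state with zero stimulus input.
// Integrates in blocks and stops when the state moves < tol (max-norm) over a
// whole block, or errors past max_time.
// [[Rcpp::export(name = ".cpp_steady_state")]]
List cpp_steady_state(NumericVector params, double h, double block,
                      double tol, double max_time) {
    const double *p = REAL(params);
    double y[4];
    // cold start: all NFkB sequestered in the complex, no mRNA / free IkBa
    y[0] = 0.0; y[1] = 0.0; y[2] = 0.0; y[3] = p[0];
    int nstep = (int)std::ceil(block / h);
    double hh = block / nstep;
    double t = 0.0, delta = R_PosInf;
    bool converged = false;
    while (t < max_time) {
        double yprev[4] = {y[0], y[1], y[2], y[3]};
        for (int s = 0; s < nstep; ++s) rk4_step(y, p, 0.0, 0.0, hh);
        t += block;
        delta = 0.0;
        for (int i = 0; i < 4; ++i) {
            double d = std::fabs(y[i] - yprev[i]);
            if (d > delta) delta = d;
        }
        if (delta < tol) { converged = true; break; }
    }
    return List::create(_["state"] = NumericVector(y, y + 4),
                        _["converged"] = converged,
                        _["delta"] = delta,
                        _["time"] = t);
}

// Phase 2: integrate over the sampling grid with a piecewise-linear IKK input
// given on the same grid. Returns the full state matrix sampled on the grid.
// [[Rcpp::export(name = ".cpp_simulate")]]
NumericMatrix cpp_simulate(NumericVector params, NumericVector y0,
                           NumericVector input, NumericVector tgrid,
                           double h) {
    const double *p = REAL(params);
    int n = tgrid.size();
    NumericMatrix out(n, 4);
    double y[4] = {y0[0], y0[1], y0[2], y0[3]};
    for (int j = 0; j < 4; ++j) out(0, j) = y[j];
    for (int i = 1; i < n; ++i) {
        double dt = tgrid[i] - tgrid[i - 1];
        int nsub = (int)std::ceil(dt / h);
        if (nsub < 1) nsub = 1;
        double hh = dt / nsub;
        double uA = input[i - 1], uB = input[i];
        for (int s = 0; s < nsub; ++s) {
            double f0 = (double)s / nsub, f1 = (double)(s + 1) / nsub;
            double u0 = uA + (uB - uA) * f0;
            double u1 = uA + (uB - uA) * f1;
            rk4_step(y, p, u0, u1, hh);
        }
        for (int j = 0; j < 4; ++j) out(i, j) = y[j];
    }
    return out;
}
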