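/* Fixed-step classical Runge-Kutta reference integrator for the
 * cleavage network.  Brute-force cross-check for the adaptive solver:
 * each save interval is subdivided into steps of at most dt. */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

static void rhs(const double *y, const double *k, double *dy)
{
    const double S = y[0], E = y[1], ES = y[2], EP = y[3], P = y[4];
    const double v_on  = k[0] * S * E;
    const double v_off = k[1] * ES;
    const double v_clv = k[2] * ES;
    const double v_lig = k[3] * EP;
    const double v_rls = k[4] * EP;
    const double v_bin = k[5] * E * P;
    dy[0] = -v_on + v_off;
    dy[1] = -v_on + v_off + v_rls - v_bin;
    dy[2] =  v_on - v_off - v_clv + v_lig;
    dy[3] =  v_clv - v_lig - v_rls + v_bin;
    dy[4] =  v_rls - v_bin;
}

SEXP dzkin_rk4(SEXP y0_, SEXP rates_, SEXP save_times_, SEXP dt_)
{
    if (LENGTH(y0_) != 5) error("y0 must have 5 elements (S, E, ES, EP, P)");
    if (LENGTH(rates_) != 6) error("rates must have 6 elements");
    const double dt = asReal(dt_);
    if (!(dt > 0)) error("dt must be positive");
    const int nt = LENGTH(save_times_);
    const double *st = REAL(save_times_);
    double y[5], k[6], k1[5], k2[5], k3[5], k4[5], yt[5];
    for (int i = 0; i < 5; ++i) y[i] = REAL(y0_)[i];
    for (int i = 0; i < 6; ++i) k[i] = REAL(rates_)[i];

    SEXP out = PROTECT(allocMatrix(REALSXP, nt, 6));
    double *o = REAL(out);
    double t = st[0];
    o[0] = t;
    for (int i = 0; i < 5; ++i) o[(i + 1) * nt] = y[i];

    for (int s = 1; s < nt; ++s) {
        const double t1 = st[s];
        if (t1 < t) { UNPROTECT(1); error("save_times must be non-decreasing"); }
        const double span = t1 - t;
        const long nstep = span > 0 ? (long)ceil(span / dt - 1e-9) : 0;
        const double h = nstep > 0 ? span / nstep : 0.0;
        for (long j = 0; j < nstep; ++j) {
            rhs(y, k, k1);
            for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
            rhs(yt, k, k2);
            for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
            rhs(yt, k, k3);
            for (int i = 0; i < 5; ++i) yt[i] = y[i] + h * k3[i];
            rhs(yt, k, k4);
            for (int i = 0; i < 5; ++i)
                y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        }
        t = t1;
        o[s] = t;
        for (int i = 0; i < 5; ++i) o[s + (i + 1) * nt] = y[i];
    }

    SEXP dimnames = PROTECT(allocVector(VECSXP, 2));
    SEXP cn = PROTECT(allocVector(STRSXP, 6));
    const char *nm[6] = {"time_s", "S", "E", "ES", "EP", "P"};
    for (int i = 0; i < 6; ++i) SET_STRING_ELT(cn, i, mkChar(nm[i]));
    SET_VECTOR_ELT(dimnames, 0, R_NilValue);
    SET_VECTOR_ELT(dimnames, 1, cn);
    setAttrib(out, R_DimNamesSymbol, dimnames);
    UNPROTECT(3);
    return out;
}
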