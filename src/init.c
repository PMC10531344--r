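#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP dzkin_rk4(SEXP y0, SEXP rates, SEXP save_times, SEXP dt);
void dzkin_initmod(void (*odeparms)(int *, double *));
void dzkin_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"dzkin_rk4", (DL_FUNC) &dzkin_rk4, 4},
    {NULL, NULL, 0}
};

/* dzkin_initmod / dzkin_derivs are resolved by deSolve through
 * getNativeSymbolInfo, so they are registered as C routines. */
static const R_CMethodDef c_entries[] = {
    {"dzkin_initmod", (DL_FUNC) &dzkin_initmod, 1},
    {"dzkin_derivs",  (DL_FUNC) &dzkin_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_dzkin(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
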