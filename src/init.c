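#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ssa_run(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_ssa_channels(SEXP, SEXP);
void tritroph_initmod(void (*)(int *, double *));
void tritroph_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"C_ssa_run",      (DL_FUNC) &C_ssa_run,      5},
    {"C_ssa_channels", (DL_FUNC) &C_ssa_channels, 2},
    {NULL, NULL, 0}
};

/* registered so deSolve can look them up by name in this DLL */
static const R_CMethodDef CEntries[] = {
    {"tritroph_initmod", (DL_FUNC) &tritroph_initmod, 1},
    {"tritroph_derivs",  (DL_FUNC) &tritroph_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_tritroph(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
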