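#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp attribute wrappers (RcppExports.cpp) */
extern SEXP _dsbkin_ssa_site_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _dsbkin_ssa_population_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);

/* deSolve-callable routines (moment_odes.c) */
extern void dsb_initmod(void (*odeparms)(int *, double *));
extern void dsb_derivs_naive(int *, double *, double *, double *, double *,
                             int *);
extern void dsb_derivs_cond(int *, double *, double *, double *, double *,
                            int *);

static const R_CallMethodDef CallEntries[] = {
    {"_dsbkin_ssa_site_cpp", (DL_FUNC) &_dsbkin_ssa_site_cpp, 5},
    {"_dsbkin_ssa_population_cpp", (DL_FUNC) &_dsbkin_ssa_population_cpp, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"dsb_initmod", (DL_FUNC) &dsb_initmod, 1},
    {"dsb_derivs_naive", (DL_FUNC) &dsb_derivs_naive, 6},
    {"dsb_derivs_cond", (DL_FUNC) &dsb_derivs_cond, 6},
    {NULL, NULL, 0}
};

void R_init_dsbkin(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
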