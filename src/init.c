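#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP viaspace_ssa_run(SEXP, SEXP, SEXP, SEXP, SEXP);

void viaspace_init_rep(void (*odeparms)(int *, double *));
void viaspace_init_acdc(void (*odeparms)(int *, double *));
void viaspace_init_ff(void (*odeparms)(int *, double *));
void viaspace_deriv_rep(int *, double *, double *, double *, double *, int *);
void viaspace_deriv_acdc(int *, double *, double *, double *, double *, int *);
void viaspace_deriv_ff(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"viaspace_ssa_run", (DL_FUNC) &viaspace_ssa_run, 5},
    {NULL, NULL, 0}
};

void R_init_viaspace(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* deriv/init symbols are looked up by name from deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
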