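#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void crn_init(void (*odeparms)(int *, double *));
void crn_derivs(int *, double *, double *, double *, double *, int *);
void mal_init(void (*odeparms)(int *, double *));
void mal_derivs(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"crn_init",   (DL_FUNC) &crn_init,   1},
    {"crn_derivs", (DL_FUNC) &crn_derivs, 6},
    {"mal_init",   (DL_FUNC) &mal_init,   1},
    {"mal_derivs", (DL_FUNC) &mal_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_apsens(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
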