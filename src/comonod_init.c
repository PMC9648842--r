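#include <stddef.h>
#include <R_ext/Rdynload.h>

void comonod_initmod(void (*odeparms)(int *, double *));
void comonod_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"comonod_initmod", (DL_FUNC) &comonod_initmod, 1},
    {"comonod_derivs",  (DL_FUNC) &comonod_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_comonod(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
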