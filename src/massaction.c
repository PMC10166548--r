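/* Mass-action ODE right-hand side for deSolve's compiled-function interface.
 *
 * The reaction network (reactant indices, sparse net stoichiometry, rate
 * constants) is loaded into static storage by ma_set_network() immediately
 * before each integration; ma_derivs() is then resolved by deSolve through
 * the package DLL.  Single-threaded by design, matching deSolve.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MA_MAX_REAC 8192
#define MA_MAX_NZ   32768

static int    ma_nreac = 0;
static int    ma_i1[MA_MAX_REAC];      /* first reactant, 0-based, -1 if none  */
static int    ma_i2[MA_MAX_REAC];      /* second reactant (may equal first)    */
static double ma_k[MA_MAX_REAC];
static int    ma_ptr[MA_MAX_REAC + 1]; /* CSR pointers into ma_sp / ma_co      */
static int    ma_sp[MA_MAX_NZ];        /* species touched by each reaction     */
static double ma_co[MA_MAX_NZ];        /* net stoichiometric coefficient       */

SEXP ma_set_network(SEXP i1, SEXP i2, SEXP ptr, SEXP sp, SEXP co, SEXP k)
{
    int m = LENGTH(k);
    int nz = LENGTH(sp);
    if (m > MA_MAX_REAC) error("mass-action network exceeds %d reactions", MA_MAX_REAC);
    if (nz > MA_MAX_NZ)  error("mass-action network exceeds %d stoichiometry entries", MA_MAX_NZ);
    ma_nreac = m;
    for (int j = 0; j < m; j++) {
        ma_i1[j] = INTEGER(i1)[j];
        ma_i2[j] = INTEGER(i2)[j];
        ma_k[j]  = REAL(k)[j];
    }
    for (int j = 0; j <= m; j++) ma_ptr[j] = INTEGER(ptr)[j];
    for (int q = 0; q < nz; q++) {
        ma_sp[q] = INTEGER(sp)[q];
        ma_co[q] = REAL(co)[q];
    }
    return R_NilValue;
}

void ma_derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    for (int s = 0; s < *neq; s++) ydot[s] = 0.0;
    for (int j = 0; j < ma_nreac; j++) {
        double v = ma_k[j];
        if (ma_i1[j] >= 0) v *= y[ma_i1[j]];
        if (ma_i2[j] >= 0) v *= y[ma_i2[j]];
        for (int q = ma_ptr[j]; q < ma_ptr[j + 1]; q++)
            ydot[ma_sp[q]] += ma_co[q] * v;
    }
}

static const R_CallMethodDef CallEntries[] = {
    {"ma_set_network", (DL_FUNC) &ma_set_network, 6},
    {NULL, NULL, 0}
};

void R_init_mmcal(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* keep dynamic lookup enabled: deSolve resolves "ma_derivs" by name */
    R_useDynamicSymbols(dll, TRUE);
}
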