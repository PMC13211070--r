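/* Hot elementwise kernels for the autodiff engine: column-broadcast
 * multiply/add (bias and channel-gate application over time) and ReLU
 * forward/backward. These sit inside every convolution block and dominated
 * pure-R training profiles. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* x: n x m numeric matrix; v: length-m vector; out[i,j] = x[i,j] * v[j] */
static SEXP colbroadcast(SEXP x, SEXP v, int add)
{
    R_xlen_t n = Rf_nrows(x), m = Rf_ncols(x);
    SEXP out = PROTECT(Rf_allocMatrix(REALSXP, (int) n, (int) m));
    const double *xp = REAL(x), *vp = REAL(v);
    double *op = REAL(out);
    for (R_xlen_t j = 0; j < m; j++) {
        const double vj = vp[j];
        const double *col = xp + j * n;
        double *oc = op + j * n;
        if (add)
            for (R_xlen_t i = 0; i < n; i++) oc[i] = col[i] + vj;
        else
            for (R_xlen_t i = 0; i < n; i++) oc[i] = col[i] * vj;
    }
    UNPROTECT(1);
    return out;
}

SEXP C_cmul(SEXP x, SEXP v) { return colbroadcast(x, v, 0); }
SEXP C_cadd(SEXP x, SEXP v) { return colbroadcast(x, v, 1); }

SEXP C_relu(SEXP x)
{
    R_xlen_t n = XLENGTH(x);
    SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
    SEXP dim = Rf_getAttrib(x, R_DimSymbol);
    if (dim != R_NilValue) Rf_setAttrib(out, R_DimSymbol, dim);
    const double *xp = REAL(x);
    double *op = REAL(out);
    for (R_xlen_t i = 0; i < n; i++) op[i] = xp[i] > 0 ? xp[i] : 0;
    UNPROTECT(1);
    return out;
}

/* gradient of ReLU: g where x > 0, else 0 */
SEXP C_relu_grad(SEXP g, SEXP x)
{
    R_xlen_t n = XLENGTH(x);
    SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
    SEXP dim = Rf_getAttrib(g, R_DimSymbol);
    if (dim != R_NilValue) Rf_setAttrib(out, R_DimSymbol, dim);
    const double *xp = REAL(x), *gp = REAL(g);
    double *op = REAL(out);
    for (R_xlen_t i = 0; i < n; i++) op[i] = xp[i] > 0 ? gp[i] : 0;
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_cmul", (DL_FUNC) &C_cmul, 2},
    {"C_cadd", (DL_FUNC) &C_cadd, 2},
    {"C_relu", (DL_FUNC) &C_relu, 1},
    {"C_relu_grad", (DL_FUNC) &C_relu_grad, 2},
    {NULL, NULL, 0}
};

void R_init_slecg(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
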