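/* Zero-lag IIR filtering hot loop: forward-backward application of a
   direct-form transposed... direct-form I recursion with odd-reflection
   end padding, per matrix column.  Kept in C because the AR recursion is
   inherently sequential and is executed hundreds of thousands of times in
   replicate simulation studies. */

#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static void filt_pass(const double *x, double *y, int n,
                      const double *b, int nb, const double *a, int na)
{
    for (int i = 0; i < n; i++) {
        double acc = 0.0;
        int kb = (nb < i + 1) ? nb : i + 1;
        for (int k = 0; k < kb; k++) acc += b[k] * x[i - k];
        int ka = (na - 1 < i) ? na - 1 : i;
        for (int k = 1; k <= ka; k++) acc -= a[k] * y[i - k];
        y[i] = acc;
    }
}

/* x: n x m real matrix; b, a: coefficients with a[0] = 1; np: requested
   odd-reflection pad length (clamped to n - 1). */
SEXP divekin_filtfilt(SEXP xs, SEXP bs, SEXP as, SEXP nps)
{
    int n = Rf_nrows(xs), m = Rf_ncols(xs);
    int np = Rf_asInteger(nps);
    int nb = Rf_length(bs), na = Rf_length(as);
    double *b = REAL(bs), *a = REAL(as), *x = REAL(xs);
    if (np > n - 1) np = n - 1;
    if (np < 0) np = 0;
    int N = n + 2 * np;
    SEXP out = PROTECT(Rf_allocMatrix(REALSXP, n, m));
    double *y = REAL(out);
    double *buf = (double *) R_alloc(N, sizeof(double));
    double *tmp = (double *) R_alloc(N, sizeof(double));
    for (int j = 0; j < m; j++) {
        const double *col = x + (size_t) j * n;
        for (int i = 0; i < np; i++) buf[i] = 2.0 * col[0] - col[np - i];
        memcpy(buf + np, col, n * sizeof(double));
        for (int i = 0; i < np; i++)
            buf[np + n + i] = 2.0 * col[n - 1] - col[n - 2 - i];
        filt_pass(buf, tmp, N, b, nb, a, na);
        for (int i = 0; i < N; i++) buf[i] = tmp[N - 1 - i];
        filt_pass(buf, tmp, N, b, nb, a, na);
        double *ycol = y + (size_t) j * n;
        for (int i = 0; i < n; i++) ycol[i] = tmp[N - 1 - np - i];
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"divekin_filtfilt", (DL_FUNC) &divekin_filtfilt, 4},
    {NULL, NULL, 0}
};

void R_init_divekin(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
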