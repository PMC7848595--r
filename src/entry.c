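/* deSolve compiled-model entry points and .Call wrappers. */
#include "emcell.h"
#include <R_ext/Rdynload.h>

static double parms[N_PARMS];

void emcell_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* single derivs entry; the variant flag in parms selects the model */
void emcell_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    if (ip[0] < N_OUT) error("nout too small");
    if ((int) parms[P_VARIANT] == 1)
        torord_rhs(*t, y, ydot, yout, parms);
    else
        ord_rhs(*t, y, ydot, yout, parms);
}

/* one-shot RHS evaluation from R: returns list(dy, out) */
SEXP C_emcell_rhs(SEXP t, SEXP y, SEXP p)
{
    if (LENGTH(p) != N_PARMS) error("parameter vector must have %d entries", N_PARMS);
    int n = LENGTH(y);
    double *pp = REAL(p);
    SEXP dy = PROTECT(allocVector(REALSXP, n));
    SEXP out = PROTECT(allocVector(REALSXP, N_OUT));
    memset(REAL(dy), 0, n * sizeof(double));
    if ((int) pp[P_VARIANT] == 1)
        torord_rhs(asReal(t), REAL(y), REAL(dy), REAL(out), pp);
    else
        ord_rhs(asReal(t), REAL(y), REAL(dy), REAL(out), pp);
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, dy);
    SET_VECTOR_ELT(res, 1, out);
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("dy"));
    SET_STRING_ELT(nm, 1, mkChar("out"));
    setAttrib(res, R_NamesSymbol, nm);
    UNPROTECT(4);
    return res;
}

/* Land model alone: returns list(dm, ta) */
SEXP C_land_rhs(SEXP m, SEXP cai_uM, SEXP p)
{
    if (LENGTH(p) != N_PARMS) error("parameter vector must have %d entries", N_PARMS);
    if (LENGTH(m) != NS_MECH) error("mechanics state must have %d entries", NS_MECH);
    SEXP dm = PROTECT(allocVector(REALSXP, NS_MECH));
    double Ta = 0.0;
    land_rhs_c(REAL(m), asReal(cai_uM), REAL(p), REAL(dm), &Ta);
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, dm);
    SET_VECTOR_ELT(res, 1, ScalarReal(Ta));
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("dm"));
    SET_STRING_ELT(nm, 1, mkChar("ta"));
    setAttrib(res, R_NamesSymbol, nm);
    UNPROTECT(3);
    return res;
}

static const R_CallMethodDef callMethods[] = {
    {"C_emcell_rhs", (DL_FUNC) &C_emcell_rhs, 3},
    {"C_land_rhs",   (DL_FUNC) &C_land_rhs,   3},
    {NULL, NULL, 0}
};

void R_init_emcell(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE); /* deSolve looks up derivs by name */
}
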