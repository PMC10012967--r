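/* Right-hand side of the two-layer adaptive phase-oscillator system.
 *
 * State layout (length 2N + 2N^2):
 *   y = [ phi1 (N), phi2 (N), kappa1 (N*N column-major), kappa2 (N*N) ]
 * Parameter layout (length 11 + N^2):
 *   p = [ N, omega1, omega2, alpha11, alpha22, alpha12, alpha21,
 *         beta, eps1, eps2, sigma, A (N*N column-major) ]
 *
 * Pairwise sines are expanded through per-node sin/cos so each evaluation
 * costs O(N^2) multiplications, not O(N^2) trig calls.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <stdlib.h>
#include <string.h>

static double *g_parms = NULL;
static int g_nparms = 0;

static void rhs_core(int N, const double *p, const double *y, double *dy)
{
    const double omega1 = p[1], omega2 = p[2];
    const double a11 = p[3], a22 = p[4], a12 = p[5], a21 = p[6];
    const double beta = p[7], eps1 = p[8], eps2 = p[9], sigma = p[10];
    const double *A = p + 11;

    const double *phi1 = y, *phi2 = y + N;
    const double *K1 = y + 2 * N, *K2 = y + 2 * N + (size_t) N * N;
    double *dphi1 = dy, *dphi2 = dy + N;
    double *dK1 = dy + 2 * N, *dK2 = dy + 2 * N + (size_t) N * N;

    const double ca11 = cos(a11), sa11 = sin(a11);
    const double ca22 = cos(a22), sa22 = sin(a22);
    const double cb = cos(beta), sb = sin(beta);

    double *s1 = (double *) R_alloc(4 * (size_t) N, sizeof(double));
    double *c1 = s1 + N, *s2 = c1 + N, *c2 = s2 + N;
    for (int i = 0; i < N; i++) {
        s1[i] = sin(phi1[i]); c1[i] = cos(phi1[i]);
        s2[i] = sin(phi2[i]); c2[i] = cos(phi2[i]);
    }

    for (int i = 0; i < N; i++) {
        dphi1[i] = 0.0;
        dphi2[i] = 0.0;
    }

    /* column-major: index (i,j) at i + N*j; loop j outer for stride-1 inner */
    for (int j = 0; j < N; j++) {
        const double s1j = s1[j], c1j = c1[j], s2j = s2[j], c2j = c2[j];
        const size_t off = (size_t) N * j;
        for (int i = 0; i < N; i++) {
            if (i == j) {
                dK1[off + i] = 0.0;
                dK2[off + i] = 0.0;
                continue;
            }
            /* sin(phi_i - phi_j) and cos(phi_i - phi_j), per layer */
            const double sd1 = s1[i] * c1j - c1[i] * s1j;
            const double cd1 = c1[i] * c1j + s1[i] * s1j;
            const double sd2 = s2[i] * c2j - c2[i] * s2j;
            const double cd2 = c2[i] * c2j + s2[i] * s2j;

            dphi1[i] += (A[off + i] + K1[off + i]) * (sd1 * ca11 + cd1 * sa11);
            dphi2[i] += K2[off + i] * (sd2 * ca22 + cd2 * sa22);

            dK1[off + i] = -eps1 * (K1[off + i] + sd1 * cb - cd1 * sb);
            dK2[off + i] = -eps2 * (K2[off + i] + sd2 * cb - cd2 * sb);
        }
    }

    const double invN = 1.0 / (double) N;
    const double ca12 = cos(a12), sa12 = sin(a12);
    const double ca21 = cos(a21), sa21 = sin(a21);
    for (int i = 0; i < N; i++) {
        /* interlayer difference phi1_i - phi2_i */
        const double sdi = s1[i] * c2[i] - c1[i] * s2[i];
        const double cdi = c1[i] * c2[i] + s1[i] * s2[i];
        dphi1[i] = omega1 - invN * dphi1[i] - sigma * (sdi * ca12 + cdi * sa12);
        dphi2[i] = omega2 - invN * dphi2[i] - sigma * (-sdi * ca21 + cdi * sa21);
    }
}

/* deSolve entry point; parameters are staged via C_duplex_set_parms() */
void duplex_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    int N = (int) g_parms[0];
    if (2 * N + 2 * N * N != *neq)
        error("duplex_derivs: state length %d does not match N = %d", *neq, N);
    rhs_core(N, g_parms, y, ydot);
}

SEXP C_duplex_set_parms(SEXP parms)
{
    int n = LENGTH(parms);
    if (g_parms) { free(g_parms); g_parms = NULL; }
    g_parms = (double *) malloc(n * sizeof(double));
    if (!g_parms) error("cannot allocate parameter storage");
    memcpy(g_parms, REAL(parms), n * sizeof(double));
    g_nparms = n;
    return R_NilValue;
}

/* one-shot RHS evaluation used by duplex_rhs() and the test oracles */
SEXP C_duplex_rhs(SEXP y, SEXP parms)
{
    int N = (int) REAL(parms)[0];
    R_xlen_t neq = 2 * N + 2 * (R_xlen_t) N * N;
    if (XLENGTH(y) != neq)
        error("state vector has length %lld, expected %lld",
              (long long) XLENGTH(y), (long long) neq);
    if (XLENGTH(parms) != 11 + (R_xlen_t) N * N)
        error("parameter vector has length %lld, expected %lld",
              (long long) XLENGTH(parms), (long long) (11 + (R_xlen_t) N * N));
    SEXP dy = PROTECT(allocVector(REALSXP, neq));
    rhs_core(N, REAL(parms), REAL(y), REAL(dy));
    UNPROTECT(1);
    return dy;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_duplex_rhs",       (DL_FUNC) &C_duplex_rhs,       2},
    {"C_duplex_set_parms", (DL_FUNC) &C_duplex_set_parms, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"duplex_derivs", (DL_FUNC) &duplex_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_duplexsep(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
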