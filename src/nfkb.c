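/* NF-kB regulatory module: 15-state mass-action ODE system with a binary
 * TNF stimulus (TR), plus analytic state/parameter Jacobians and the
 * augmented forward-sensitivity right-hand side.
 *
 * Parameter block layout handed over by deSolve's initfunc:
 *   p[0..29]  theta, Table-1 order (see R/nfkb.R)
 *   p[30]     TR   (constant within an integration segment)
 *   p[31]     nf   number of sensitivity columns (0 for the plain rhs)
 *   p[32..61] 0-based indices of the free parameters (first nf used)
 *
 * State order:
 *   0 IKKn  1 IKKa  2 IKKi  3 (IKKa|IkBa)  4 (IKKa|IkBa|NFkB)
 *   5 NFkB  6 NFkBn 7 A20   8 A20t  9 IkBa 10 IkBan 11 IkBat
 *  12 (IkBa|NFkB) 13 (IkBan|NFkBn) 14 cgen_t
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NSTATE 30 /* max parms used below */
#define NX 15
#define NP 30

static double p[62];

void nfkb_init(void (*odeparms)(int *, double *))
{
    int N = 62;
    odeparms(&N, p);
}

#define A1   th[0]
#define A2   th[1]
#define T1   th[2]
#define A3   th[3]
#define T2   th[4]
#define C1A  th[5]
#define C2A  th[6]
#define C3A  th[7]
#define C4A  th[8]
#define C5A  th[9]
#define C6A  th[10]
#define C1   th[11]
#define C2   th[12]
#define C3   th[13]
#define C4   th[14]
#define C5   th[15]
#define K1   th[16]
#define K2   th[17]
#define K3   th[18]
#define KPROD th[19]
#define KDEG th[20]
#define KV   th[22]
#define I1   th[23]
#define E2A  th[24]
#define I1A  th[25]
#define E1A  th[26]
#define C1C  th[27]
#define C2C  th[28]
#define C3C  th[29]

static void rhs_core(const double *th, double TR, const double *x, double *f)
{
    f[0]  = KPROD - KDEG * x[0] - TR * K1 * x[0];
    f[1]  = TR * K1 * x[0] - (K3 + KDEG) * x[1] - TR * K2 * x[1] * x[7]
            - A2 * x[1] * x[9] + T1 * x[3] - A3 * x[1] * x[12] + T2 * x[4];
    f[2]  = K3 * x[1] + TR * K2 * x[1] * x[7] - KDEG * x[2];
    f[3]  = A2 * x[1] * x[9] - T1 * x[3];
    f[4]  = A3 * x[1] * x[12] - T2 * x[4];
    f[5]  = C6A * x[12] - A1 * x[5] * x[9] + T2 * x[4] - I1 * x[5];
    f[6]  = I1 * KV * x[5] - A1 * x[10] * x[6];
    f[7]  = C4 * x[8] - C5 * x[7];
    f[8]  = C2 + C1 * x[6] - C3 * x[8];
    f[9]  = -A2 * x[1] * x[9] - A1 * x[9] * x[5] + C4A * x[11]
            - C5A * x[9] - I1A * x[9] + E1A * x[10];
    f[10] = -A1 * x[10] * x[6] + I1A * KV * x[9] - E1A * KV * x[10];
    f[11] = C2A + C1A * x[6] - C3A * x[11];
    f[12] = A1 * x[9] * x[5] - C6A * x[12] - A3 * x[1] * x[12] + E2A * x[13];
    f[13] = A1 * x[10] * x[6] - E2A * KV * x[13];
    f[14] = C2C + C1C * x[6] - C3C * x[14];
    /* rate constants are per second; the model clock is in minutes */
    for (int i = 0; i < NX; i++) f[i] *= 60.0;
}

/* J[i + NX*j] = d f_i / d x_j, column-major */
static void jac_state(const double *th, double TR, const double *x, double *J)
{
    int i;
    for (i = 0; i < NX * NX; i++) J[i] = 0.0;
#define JX(i, j) J[(i) + NX * (j)]
    JX(0, 0)  = -KDEG - TR * K1;
    JX(1, 0)  = TR * K1;
    JX(1, 1)  = -(K3 + KDEG) - TR * K2 * x[7] - A2 * x[9] - A3 * x[12];
    JX(1, 3)  = T1;
    JX(1, 4)  = T2;
    JX(1, 7)  = -TR * K2 * x[1];
    JX(1, 9)  = -A2 * x[1];
    JX(1, 12) = -A3 * x[1];
    JX(2, 1)  = K3 + TR * K2 * x[7];
    JX(2, 2)  = -KDEG;
    JX(2, 7)  = TR * K2 * x[1];
    JX(3, 1)  = A2 * x[9];
    JX(3, 3)  = -T1;
    JX(3, 9)  = A2 * x[1];
    JX(4, 1)  = A3 * x[12];
    JX(4, 4)  = -T2;
    JX(4, 12) = A3 * x[1];
    JX(5, 4)  = T2;
    JX(5, 5)  = -A1 * x[9] - I1;
    JX(5, 9)  = -A1 * x[5];
    JX(5, 12) = C6A;
    JX(6, 5)  = I1 * KV;
    JX(6, 6)  = -A1 * x[10];
    JX(6, 10) = -A1 * x[6];
    JX(7, 7)  = -C5;
    JX(7, 8)  = C4;
    JX(8, 6)  = C1;
    JX(8, 8)  = -C3;
    JX(9, 1)  = -A2 * x[9];
    JX(9, 5)  = -A1 * x[9];
    JX(9, 9)  = -A2 * x[1] - A1 * x[5] - C5A - I1A;
    JX(9, 10) = E1A;
    JX(9, 11) = C4A;
    JX(10, 6)  = -A1 * x[10];
    JX(10, 9)  = I1A * KV;
    JX(10, 10) = -A1 * x[6] - E1A * KV;
    JX(11, 6)  = C1A;
    JX(11, 11) = -C3A;
    JX(12, 1)  = -A3 * x[12];
    JX(12, 5)  = A1 * x[9];
    JX(12, 9)  = A1 * x[5];
    JX(12, 12) = -C6A - A3 * x[1];
    JX(12, 13) = E2A;
    JX(13, 6)  = A1 * x[10];
    JX(13, 10) = A1 * x[6];
    JX(13, 13) = -E2A * KV;
    JX(14, 6)  = C1C;
    JX(14, 14) = -C3C;
#undef JX
    for (i = 0; i < NX * NX; i++) J[i] *= 60.0;
}

/* Jp[i + NX*j] = d f_i / d theta_j, column-major, 15 x 30 */
static void jac_par(const double *th, double TR, const double *x, double *Jp)
{
    int i;
    for (i = 0; i < NX * NP; i++) Jp[i] = 0.0;
#define JP(i, j) Jp[(i) + NX * (j)]
    /* a1 */
    JP(5, 0)  = -x[5] * x[9];
    JP(6, 0)  = -x[10] * x[6];
    JP(9, 0)  = -x[9] * x[5];
    JP(10, 0) = -x[10] * x[6];
    JP(12, 0) = x[9] * x[5];
    JP(13, 0) = x[10] * x[6];
    /* a2 */
    JP(1, 1) = -x[1] * x[9];
    JP(3, 1) = x[1] * x[9];
    JP(9, 1) = -x[1] * x[9];
    /* t1 */
    JP(1, 2) = x[3];
    JP(3, 2) = -x[3];
    /* a3 */
    JP(1, 3)  = -x[1] * x[12];
    JP(4, 3)  = x[1] * x[12];
    JP(12, 3) = -x[1] * x[12];
    /* t2 */
    JP(1, 4) = x[4];
    JP(4, 4) = -x[4];
    JP(5, 4) = x[4];
    /* c1a, c2a, c3a */
    JP(11, 5) = x[6];
    JP(11, 6) = 1.0;
    JP(11, 7) = -x[11];
    /* c4a, c5a */
    JP(9, 8) = x[11];
    JP(9, 9) = -x[9];
    /* c6a */
    JP(5, 10)  = x[12];
    JP(12, 10) = -x[12];
    /* c1, c2, c3 */
    JP(8, 11) = x[6];
    JP(8, 12) = 1.0;
    JP(8, 13) = -x[8];
    /* c4, c5 */
    JP(7, 14) = x[8];
    JP(7, 15) = -x[7];
    /* k1 */
    JP(0, 16) = -TR * x[0];
    JP(1, 16) = TR * x[0];
    /* k2 */
    JP(1, 17) = -TR * x[1] * x[7];
    JP(2, 17) = TR * x[1] * x[7];
    /* k3 */
    JP(1, 18) = -x[1];
    JP(2, 18) = x[1];
    /* kprod, kdeg */
    JP(0, 19) = 1.0;
    JP(0, 20) = -x[0];
    JP(1, 20) = -x[1];
    JP(2, 20) = -x[2];
    /* NF (index 21): enters only through the initial condition */
    /* kv */
    JP(6, 22)  = I1 * x[5];
    JP(10, 22) = I1A * x[9] - E1A * x[10];
    JP(13, 22) = -E2A * x[13];
    /* i1 */
    JP(5, 23) = -x[5];
    JP(6, 23) = KV * x[5];
    /* e2a */
    JP(12, 24) = x[13];
    JP(13, 24) = -KV * x[13];
    /* i1a */
    JP(9, 25)  = -x[9];
    JP(10, 25) = KV * x[9];
    /* e1a */
    JP(9, 26)  = x[10];
    JP(10, 26) = -KV * x[10];
    /* c1c, c2c, c3c */
    JP(14, 27) = x[6];
    JP(14, 28) = 1.0;
    JP(14, 29) = -x[14];
#undef JP
    for (i = 0; i < NX * NP; i++) Jp[i] *= 60.0;
}

void nfkb_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    rhs_core(p, p[30], y, ydot);
}

/* augmented system: states followed by sensitivity columns (column-major) */
void nfkb_sens(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double J[NX * NX], Jp[NX * NP];
    int nf = (int) p[31];
    int j, i, k;
    rhs_core(p, p[30], y, ydot);
    jac_state(p, p[30], y, J);
    jac_par(p, p[30], y, Jp);
    for (j = 0; j < nf; j++) {
        int idx = (int) p[32 + j];
        double *S = y + NX * (1 + j);
        double *Sd = ydot + NX * (1 + j);
        for (i = 0; i < NX; i++) {
            double acc = Jp[i + NX * idx];
            for (k = 0; k < NX; k++)
                acc += J[i + NX * k] * S[k];
            Sd[i] = acc;
        }
    }
}

/* .Call accessors for tests, resting-state polish and S(0) */
SEXP C_nfkb_rhs(SEXP x, SEXP tr, SEXP theta)
{
    SEXP out = PROTECT(allocVector(REALSXP, NX));
    rhs_core(REAL(theta), asReal(tr), REAL(x), REAL(out));
    UNPROTECT(1);
    return out;
}

SEXP C_nfkb_jac(SEXP x, SEXP tr, SEXP theta)
{
    SEXP jx = PROTECT(allocMatrix(REALSXP, NX, NX));
    SEXP jp = PROTECT(allocMatrix(REALSXP, NX, NP));
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    jac_state(REAL(theta), asReal(tr), REAL(x), REAL(jx));
    jac_par(REAL(theta), asReal(tr), REAL(x), REAL(jp));
    SET_VECTOR_ELT(out, 0, jx);
    SET_VECTOR_ELT(out, 1, jp);
    UNPROTECT(3);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_nfkb_rhs", (DL_FUNC) &C_nfkb_rhs, 3},
    {"C_nfkb_jac", (DL_FUNC) &C_nfkb_jac, 3},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"nfkb_init",  (DL_FUNC) &nfkb_init,  1},
    {"nfkb_deriv", (DL_FUNC) &nfkb_deriv, 6},
    {"nfkb_sens",  (DL_FUNC) &nfkb_sens,  6},
    {NULL, NULL, 0}
};

void R_init_iterid(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
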