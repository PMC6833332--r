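/* Compiled right-hand side for the age-structured senescence model,
 * in the standard deSolve compiled-model form.
 *
 * Parameter vector layout (padded to 4*SEN_MAXN + 3 doubles on the R side):
 *   p[0]                  N (number of proliferative doubling-age classes)
 *   p[1      .. N]        division rates       m_{P_i P_{i+1}},  i = 0..N-1
 *   p[N+1    .. 2N]       senescence-jump rates m_{P_i S}
 *   p[2N+1   .. 3N]       growth-arrest rates   m_{P_i G}
 *   p[3N+1   .. 4N]       apoptosis rates       m_{P_i A}
 *   p[4N+1]               m_GS   (growth-arrested -> senescent)
 *   p[4N+2]               m_AD   (apoptotic -> dead)
 *
 * State vector: y[0..N-1] = P_i, y[N] = G, y[N+1] = A, y[N+2] = S, y[N+3] = D.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define SEN_MAXN 512

static double senp[4 * SEN_MAXN + 3];

void senodyn_initmod(void (*odeparms)(int *, double *))
{
    int n = 4 * SEN_MAXN + 3;
    odeparms(&n, senp);
}

void senodyn_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int N = (int) (senp[0] + 0.5);
    const double *div = senp + 1;
    const double *sen = senp + 1 + N;
    const double *arr = senp + 1 + 2 * N;
    const double *apo = senp + 1 + 3 * N;
    double mGS = senp[4 * N + 1];
    double mAD = senp[4 * N + 2];
    double G = y[N], A = y[N + 1];
    double sumSen = 0.0, sumArr = 0.0, sumApo = 0.0;

    for (int i = 0; i < N; i++) {
        double exit = div[i] + sen[i] + arr[i] + apo[i];
        ydot[i] = -exit * y[i];
        if (i > 0)
            ydot[i] += 2.0 * div[i - 1] * y[i - 1];
        sumSen += sen[i] * y[i];
        sumArr += arr[i] * y[i];
        sumApo += apo[i] * y[i];
    }
    /* G, A, S, D */
    ydot[N]     = sumArr - mGS * G;
    ydot[N + 1] = sumApo - mAD * A;
    ydot[N + 2] = 2.0 * div[N - 1] * y[N - 1] + sumSen + mGS * G;
    ydot[N + 3] = mAD * A;
}

static const R_CMethodDef cMethods[] = {
    {"senodyn_derivs", (DL_FUNC) &senodyn_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_senodyn(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
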