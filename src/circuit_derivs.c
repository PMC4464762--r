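/* Hill-kinetics right-hand side for an arbitrary signed topology,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * The parameter vector is padded to a fixed length CD_NP so a single
 * compiled symbol serves every network. Layout:
 *   p[0] n nodes, p[1] input node (1-based), p[2] nAct, p[3] nInh,
 *   p[4] Wp, p[5] Wn, p[6] delta,
 *   then nAct activation edges as (from, to, a, b)
 *   then nInh inhibition edges as (from, to, c, d).
 *
 * Non-input node i:
 *   dx_i/dt = [sum_act Wp * a * x_j^2 / (delta * b + x_j^2)]
 *             * [prod_inh 1 / (c + Wn * d * x_j^2)] + 0.1 - x_i
 * Input node (signal consumed by repair; no production, no weighting):
 *   dx_in/dt = -sum_inh x_j^2 / (c + x_j^2) * ramp(x_in)
 * with ramp(x) = 1 for x >= CD_RAMP, x / CD_RAMP on (0, CD_RAMP), 0 below.
 * The ramp makes the cleared signal absorbing: without it the printed
 * decay stays negative whenever repair genes are basally expressed and
 * the signal would fall below zero; a hard zero gate would make the
 * step-size control chatter at the discontinuity.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define CD_NP   4096
#define CD_MAXN 64
#define CD_RAMP 1e-3

static double cd_p[CD_NP];

void cd_initmod(void (*odeparms)(int *, double *))
{
    int n = CD_NP;
    odeparms(&n, cd_p);
}

void cd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int n   = (int) cd_p[0];
    const int inp = (int) cd_p[1] - 1;
    const int na  = (int) cd_p[2];
    const int ni  = (int) cd_p[3];
    const double Wp  = cd_p[4];
    const double Wn  = cd_p[5];
    const double del = cd_p[6];
    double act[CD_MAXN], prod[CD_MAXN];
    double inhInput = 0.0;
    const double *e;
    int i, k;

    for (i = 0; i < n; i++) { act[i] = 0.0; prod[i] = 1.0; }

    e = cd_p + 7;
    for (k = 0; k < na; k++, e += 4) {
        const int from = (int) e[0] - 1, to = (int) e[1] - 1;
        double x = y[from];
        if (x < 0.0) x = 0.0;
        if (to != inp)                      /* input has no production  */
            act[to] += Wp * e[2] * x * x / (del * e[3] + x * x);
    }
    for (k = 0; k < ni; k++, e += 4) {
        const int from = (int) e[0] - 1, to = (int) e[1] - 1;
        double x = y[from];
        if (x < 0.0) x = 0.0;
        if (to == inp)
            inhInput += x * x / (e[2] + x * x);
        else
            prod[to] *= 1.0 / (e[2] + Wn * e[3] * x * x);
    }
    for (i = 0; i < n; i++) {
        if (i == inp) {
            double ramp = y[i] / CD_RAMP;
            if (ramp > 1.0) ramp = 1.0;
            if (ramp < 0.0) ramp = 0.0;
            ydot[i] = -inhInput * ramp;
        } else {
            ydot[i] = act[i] * prod[i] + 0.1 - y[i];
        }
    }
}

static const R_CMethodDef cMethods[] = {
    {"cd_initmod", (DL_FUNC) &cd_initmod, 1},
    {"cd_derivs",  (DL_FUNC) &cd_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_CircuitDesign(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
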