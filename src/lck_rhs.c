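/* Generic mass-action network right-hand side for deSolve's compiled-model
 * interface.  The network (rate constants, reactant indices, stoichiometry
 * triplets) is encoded into the parms vector by encode_network() on the R
 * side; see R/network.R for the layout.  All reactions are uni- or
 * bimolecular, so rates stay finite for any (possibly negative) state. */

#include <R.h>
#include <R_ext/Rdynload.h>

#define LCK_PARMS_LEN 4096
#define LCK_MAX_RX 512

static double parms[LCK_PARMS_LEN];

void lck_initmod(void (*odeparms)(int *, double *))
{
    int N = LCK_PARMS_LEN;
    odeparms(&N, parms);
}

void lck_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int ns = (int) parms[0];
    const int nr = (int) parms[1];
    const int nz = (int) parms[2];
    const double *k  = parms + 3;
    const double *r1 = k + nr;
    const double *r2 = r1 + nr;
    const double *st = r2 + nr;
    double v[LCK_MAX_RX];
    int i, j, z;

    for (j = 0; j < nr; j++) {
        double rate = k[j] * y[(int) r1[j]];
        int b = (int) r2[j];
        if (b >= 0)
            rate *= y[b];
        v[j] = rate;
    }
    for (i = 0; i < ns; i++)
        ydot[i] = 0.0;
    for (z = 0; z < nz; z++)
        ydot[(int) st[3 * z + 1]] += st[3 * z + 2] * v[(int) st[3 * z]];
}

static const R_CMethodDef CEntries[] = {
    {"lck_derivs",  (DL_FUNC) &lck_derivs,  6},
    {"lck_initmod", (DL_FUNC) &lck_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_lckautoreg(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
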