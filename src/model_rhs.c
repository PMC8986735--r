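/* Compiled right-hand side of the 17-state tumor-compartment PK-PD model.
 *
 * Mirrors the R reference implementation rhs_r() exactly; both consume the
 * packed parameter vector produced by pack_parms(). Layout (0-based):
 *   0..55   scalar parameters (see pack_parms in R/rhs.R, shifted by one)
 *   56      number of nanoparticle dose times, 57..96 the times (weeks)
 *   97      number of IP antibody doses, 98 k_abs,
 *   99..138 IP dose times, 139..178 per-dose peritoneal concentrations (nM)
 */
#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NPARMS 179
#define MAXDOSE 40

static double p[NPARMS];

void init_mir22(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void derivs_mir22(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double NP = y[0], NV = y[1], NI = y[2], NM = y[3], NC = y[4];
    const double CM = y[5];
    const double CAbP = y[6], CAbV = y[7], CAbI = y[8], CAbM = y[9];
    const double CDP = y[10], CDV = y[11], CDI = y[12], CDC = y[13];
    const double CE = y[14], CP = y[15], B = y[16];
    const double tt = *t;

    const double Q = (p[1] > 0.5) ? p[2] : p[2] * exp(-p[3] * B);
    const double S = (p[4] > 0.5) ? p[5]
                                  : p[5] * exp(-p[6] * B) + p[7] * exp(-p[8] * B);
    const int ok = B >= p[55];
    const double VBV = p[9] * B, VBC = p[10] * B, VBI = p[11] * B;
    const double QB = Q * B;

    const double ex_np = ok ? (NV / VBV - NP / p[0]) * QB : 0.0;
    ydot[0] = ex_np - p[12] * NP;
    ydot[1] = -ex_np - p[13] * S * NV;
    ydot[2] = p[13] * S * NV - p[14] * NI;
    ydot[3] = p[14] * NI - p[15] * NM;
    ydot[4] = p[15] * NM - p[16] * NC;

    /* miRNA-22 release: payload clock restarts at each NP injection */
    double rel = 0.0;
    const int n_np = (int) p[56];
    if (ok && n_np > 0) {
        double last = -1.0;
        for (int i = 0; i < n_np; i++)
            if (p[57 + i] <= tt && p[57 + i] > last) last = p[57 + i];
        if (last >= 0.0)
            rel = p[19] * NC * p[20] * exp(-p[19] * (tt - last)) / VBC;
    }
    ydot[5] = p[17] / (1.0 + p[18] * B) + rel - p[21] * CM;

    /* peritoneal absorption forcing (mouse IP antibody) */
    double ip_in = 0.0;
    const int n_ip = (int) p[97];
    for (int i = 0; i < n_ip; i++) {
        const double tj = p[99 + i];
        if (tj <= tt)
            ip_in += p[98] * p[139 + i] * exp(-p[98] * (tt - tj));
    }
    const double ex_ab = ok ? (CAbV - CAbP) * QB : 0.0;
    ydot[6] = ip_in + (ex_ab - p[22] * CAbP) / p[23];
    ydot[7] = (ok ? (CAbP - CAbV) * QB / VBV : 0.0) - p[24] * S * CAbV;
    ydot[8] = p[24] * S * CAbV - p[25] * CAbI;
    ydot[9] = p[25] * CAbI - p[26] * CAbM;

    const double ex_d = ok ? (CDV - CDP) * QB : 0.0;
    ydot[10] = (ex_d - p[27] * CDP) / p[28];
    const double J = -p[29] * (CDV - CDI);
    ydot[11] = ok ? ((CDP - CDV) * QB + J * S) / VBV : 0.0;
    ydot[12] = (ok ? -J * S / VBI : 0.0) - p[30] * CDI;
    ydot[13] = p[31] * CDI - p[32] * CDC;

    ydot[14] = p[33] * (1.0 + p[34] * B / (p[35] + B)) -
               p[36] * (1.0 + p[37] * CM / (p[38] + CM)) * CE;
    ydot[15] = p[39] * (1.0 + p[40] * CE / (p[41] + CE)) -
               p[42] * (1.0 + p[43] * CAbM / (p[44] + CAbM)) * CP;
    ydot[16] = p[45] * (1.0 + p[46] * CE / (p[47] + CE)) *
                   (1.0 - B / p[48]) * B -
               p[49] / (1.0 + p[50] * CP) * B -
               p[51] * (CDC / (p[52] * (1.0 + p[53] * CE / (p[54] + CE)) +
                               CDC)) * B;
}

static const R_CMethodDef CEntries[] = {
    {"init_mir22",   (DL_FUNC) &init_mir22,   1},
    {"derivs_mir22", (DL_FUNC) &derivs_mir22, 6},
    {NULL, NULL, 0}
};

void R_init_mir22sim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
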