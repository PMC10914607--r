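/* Compiled right-hand side of the batch cross-feeding ODE system,
 * in the standard deSolve compiled-model form. The parameter layout is
 * produced by pack_parms() in R/model-fluxes.R and padded to PARMS_LEN
 * doubles so the initializer knows its length.
 *
 * State vector: [G, x_1..x_nM, y_1..y_nS, (I, P when pathway enabled)].
 * Fluxes are evaluated on max(component, 0) to guard against tiny
 * negative solver excursions.
 */
#include <math.h>
#include <R.h>

#define PARMS_LEN 4096

static double parms[PARMS_LEN];

void crossfeed_initmod(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

static double pos(double v) { return v > 0.0 ? v : 0.0; }

void crossfeed_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const int ns = (int) parms[0];
    const int nm = (int) parms[1];
    const int tox = (int) parms[2];
    const int path = (int) parms[3];
    const double hill = parms[4];
    const double kappa = parms[5];
    const double conv_vmax = parms[6];
    const double conv_km = parms[7];
    const double *delta = parms + 8;       /* unused directly: folded in leak */
    const double *thr = parms + 8 + nm;
    const int base0 = 8 + 2 * nm;
    const int stride = 7 + 4 * nm;
    int i, k;

    (void) neq; (void) t; (void) yout; (void) ip; (void) delta;

    double G = pos(y[0]);
    double I = path ? pos(y[1 + nm + ns]) : 0.0;

    /* toxicity attenuation factor, shared by all strains */
    double toxf = 1.0;
    if (tox) {
        for (k = 0; k < nm; k++) {
            if (thr[k] > 0.0) {
                double r = pos(y[1 + k]) / thr[k];
                toxf /= 1.0 + pow(r, hill);
            }
        }
    }

    ydot[0] = 0.0;
    for (k = 0; k < nm; k++) ydot[1 + k] = 0.0;
    if (path) { ydot[1 + nm + ns] = 0.0; ydot[2 + nm + ns] = 0.0; }

    for (i = 0; i < ns; i++) {
        const double *s = parms + base0 + i * stride;
        const double vg = s[0], kg = s[1], gamG = s[2], eta = s[3];
        const double sumphi = s[4], phi_path = s[5];
        const int downstream = s[6] > 0.5;
        const double *leak = s + 7;
        const double *vmax = s + 7 + nm;
        const double *km = s + 7 + 2 * nm;
        const double *gam = s + 7 + 3 * nm;
        const double yi = pos(y[1 + nm + i]);

        double jg = vg * G / (kg + G);           /* glucose uptake flux */
        double grow = gamG * (1.0 - sumphi) * jg; /* glucose-limited term */

        ydot[0] -= jg * yi;
        if (path && phi_path > 0.0)
            ydot[1 + nm + ns] += kappa * phi_path * jg * yi;

        for (k = 0; k < nm; k++) {
            if (leak[k] > 0.0)
                ydot[1 + k] += leak[k] * jg * yi;
            if (km[k] > 0.0) {               /* auxotrophic for metabolite k */
                double x = pos(y[1 + k]);
                double jm = vmax[k] * x / (km[k] + x);
                ydot[1 + k] -= jm * yi;
                double gm = gam[k] * jm;
                if (gm < grow) grow = gm;
            }
        }
        if (tox) grow *= toxf;
        ydot[1 + nm + i] = (grow - eta) * yi;

        if (downstream) {
            double conv = conv_vmax * I / (conv_km + I) * yi;
            ydot[1 + nm + ns] -= conv;
            ydot[2 + nm + ns] += conv;
        }
    }
}
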