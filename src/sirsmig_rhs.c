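/* Seasonal derivative fields for the two-habitat multi-strain SIRS model,
 * in the standard deSolve compiled-model form.
 *
 * State order (10): Sr, Ir1, Ir2, Ir3, Rr, Sm, Im1, Im2, Im3, Rm
 * Parameter order (13): b, d, sigma, gamma, mu, nu1, nu2,
 *                       beta1, beta2, beta3, alpha1, alpha2, alpha3
 */
#include <R.h>

static double parms[13];

#define P_B      parms[0]
#define P_D      parms[1]
#define P_SIGMA  parms[2]
#define P_GAMMA  parms[3]
#define P_MU     parms[4]
#define P_NU1    parms[5]
#define P_NU2    parms[6]
#define P_BETA   (parms + 7)
#define P_ALPHA  (parms + 10)

void sirsmig_init(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

/* Shared-habitat season: cross-type transmission pools resident and migrant
 * infecteds, reproduction with density dependence (1 - gamma*N), recovery at
 * nu1 for both host types. */
void sirsmig_shared(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double Sr = y[0], Rr = y[4], Sm = y[5], Rm = y[9];
    const double *Ir = y + 1, *Im = y + 6;

    double N = 0.0;
    for (int k = 0; k < 10; k++) N += y[k];
    const double f = 1.0 - P_GAMMA * N;

    double sumIr = 0.0, sumIm = 0.0, foi_r = 0.0, foi_m = 0.0;
    for (int i = 0; i < 3; i++) {
        const double pool = Ir[i] + Im[i];
        sumIr += Ir[i];
        sumIm += Im[i];
        foi_r += P_BETA[i] * pool; /* per-susceptible infection hazard */
        foi_m += P_BETA[i] * pool;
    }

    ydot[0] = -Sr * foi_r + P_MU * Rr
              + (P_B * (Sr + Rr) + (P_B + P_SIGMA) * sumIr) * f
              - P_D * Sr;
    ydot[5] = -Sm * foi_m + P_MU * Rm
              + (P_B * (Sm + Rm) + (P_B + P_SIGMA) * sumIm) * f
              - P_D * Sm;
    for (int i = 0; i < 3; i++) {
        const double pool = Ir[i] + Im[i];
        ydot[1 + i] = P_BETA[i] * Sr * pool - P_NU1 * Ir[i]
                      - (P_D + P_ALPHA[i]) * Ir[i];
        ydot[6 + i] = P_BETA[i] * Sm * pool - P_NU1 * Im[i]
                      - (P_D + P_ALPHA[i]) * Im[i];
    }
    ydot[4] = P_NU1 * sumIr - (P_MU + P_D) * Rr;
    ydot[9] = P_NU1 * sumIm - (P_MU + P_D) * Rm;
}

/* Separate-habitat season: within-type transmission only, no reproduction,
 * residents recover at nu1 and migrants at nu2. */
void sirsmig_separate(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double Sr = y[0], Rr = y[4], Sm = y[5], Rm = y[9];
    const double *Ir = y + 1, *Im = y + 6;

    double sumIr = 0.0, sumIm = 0.0, foi_r = 0.0, foi_m = 0.0;
    for (int i = 0; i < 3; i++) {
        sumIr += Ir[i];
        sumIm += Im[i];
        foi_r += P_BETA[i] * Ir[i];
        foi_m += P_BETA[i] * Im[i];
    }

    ydot[0] = -Sr * foi_r + P_MU * Rr - P_D * Sr;
    ydot[5] = -Sm * foi_m + P_MU * Rm - P_D * Sm;
    for (int i = 0; i < 3; i++) {
        ydot[1 + i] = P_BETA[i] * Sr * Ir[i] - P_NU1 * Ir[i]
                      - (P_D + P_ALPHA[i]) * Ir[i];
        ydot[6 + i] = P_BETA[i] * Sm * Im[i] - P_NU2 * Im[i]
                      - (P_D + P_ALPHA[i]) * Im[i];
    }
    ydot[4] = P_NU1 * sumIr - (P_MU + P_D) * Rr;
    ydot[9] = P_NU2 * sumIm - (P_MU + P_D) * Rm;
}
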