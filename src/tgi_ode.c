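/* Right-hand sides of the TGI ODE systems, in the deSolve compiled-model
 * convention (initfunc receives the parameter vector, derivs is called by
 * lsoda).  Concentration curves are passed as sums of terms
 *   coef * (t - t0)^pow * exp(-rate * (t - t0)),  t >= t0,  pow in {0, 1},
 * which is the general closed form of linear compartmental PK under
 * superposition of bolus/first-order-absorption doses.
 *
 * Parameter vectors are padded on the R side to the fixed lengths below.
 */

#include <R.h>
#include <math.h>

#define MAXTERMS 192            /* max exponential terms per drug */

/* ---- single-agent (4-state Simeoni) model --------------------------- */
/* parms: lambda0, lambda1, psi, k1, k2, nterms, terms[4*MAXTERMS] */
#define NP_SINGLE (6 + 4 * MAXTERMS)
static double p_single[NP_SINGLE];

void tgi_init_single(void (*odeparms)(int *, double *))
{
    int N = NP_SINGLE;
    odeparms(&N, p_single);
}

static double conc_eval(double t, int n, const double *terms)
{
    double c = 0.0;
    int m;
    for (m = 0; m < n; m++) {
        const double *tm = terms + 4 * m;
        double tau = t - tm[0];
        double e;
        if (tau < 0.0) continue;
        e = tm[1] * exp(-tm[2] * tau);
        if (tm[3] > 0.5) e *= tau;
        c += e;
    }
    return c;
}

/* (1 + z^psi)^(1/psi), computed stably for large z */
static double psi_denom(double z, double psi)
{
    if (z <= 0.0) return 1.0;
    if (z <= 1.0) return pow(1.0 + pow(z, psi), 1.0 / psi);
    return z * pow(1.0 + pow(z, -psi), 1.0 / psi);
}

void tgi_deriv_single(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double lambda0 = p_single[0], lambda1 = p_single[1],
                 psi = p_single[2], k1 = p_single[3], k2 = p_single[4];
    const int n = (int) p_single[5];
    const double c = conc_eval(*t, n, p_single + 6);
    const double w = y[0] + y[1] + y[2] + y[3];
    const double fp = lambda0 * y[0] / psi_denom((lambda0 / lambda1) * w, psi);
    const double kill = k2 * c;

    ydot[0] = fp - kill * y[0];
    ydot[1] = kill * y[0] - k1 * y[1];
    ydot[2] = k1 * (y[1] - y[2]);
    ydot[3] = k1 * (y[2] - y[3]);
}

/* ---- two-drug 16-state model ---------------------------------------- */
/* parms: lambda0, lambda1, psi, k1a, k2a, k1b, k2b, gamma,
 *        flag (0 = gamma model, 1 = cross-potency "first attempt"),
 *        k2a_b, k2b_a,
 *        ntermsA, termsA[4*MAXTERMS], ntermsB, termsB[4*MAXTERMS]
 * state: x[i][j] flattened row-major, index 4*i + j;
 *        i = damage stage by drug A, j = by drug B.
 */
#define NP_COMBO (11 + 2 * (1 + 4 * MAXTERMS))
static double p_combo[NP_COMBO];

void tgi_init_combo(void (*odeparms)(int *, double *))
{
    int N = NP_COMBO;
    odeparms(&N, p_combo);
}

void tgi_deriv_combo(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double lambda0 = p_combo[0], lambda1 = p_combo[1],
                 psi = p_combo[2], k1a = p_combo[3], k2a = p_combo[4],
                 k1b = p_combo[5], k2b = p_combo[6], gamma = p_combo[7];
    const int first_attempt = p_combo[8] > 0.5;
    const double k2a_b = p_combo[9], k2b_a = p_combo[10];
    const int nA = (int) p_combo[11];
    const double *termsA = p_combo + 12;
    const int nB = (int) p_combo[12 + 4 * MAXTERMS];
    const double *termsB = p_combo + 13 + 4 * MAXTERMS;

    const double ca = conc_eval(*t, nA, termsA);
    const double cb = conc_eval(*t, nB, termsB);

    double w = 0.0;
    int i, j;
    for (i = 0; i < 16; i++) w += y[i];

    {
        const double fp =
            lambda0 * y[0] / psi_denom((lambda0 / lambda1) * w, psi);
        const double g = first_attempt ? 0.0 : gamma * ca * cb;
        const double kA0 = k2a * ca;                     /* on x00        */
        const double kB0 = k2b * cb;
        const double kAd = (first_attempt ? k2a_b : k2a) * ca; /* on x0j, j>0 */
        const double kBd = (first_attempt ? k2b_a : k2b) * cb; /* on xi0, i>0 */

        for (i = 0; i < 4; i++) {
            for (j = 0; j < 4; j++) {
                const int id = 4 * i + j;
                double d = 0.0;
                if (i == 0 && j == 0) {
                    d = fp - (kA0 + kB0 + g) * y[0];
                } else {
                    /* drug-A cascade terms */
                    if (i == 1)
                        d += (j == 0 ? kA0 : kAd) * y[j] - k1a * y[id];
                    else if (i >= 2)
                        d += k1a * (y[4 * (i - 1) + j] - y[id]);
                    /* drug-B cascade terms */
                    if (j == 1)
                        d += (i == 0 ? kB0 : kBd) * y[4 * i] - k1b * y[id];
                    else if (j >= 2)
                        d += k1b * (y[4 * i + (j - 1)] - y[id]);
                    /* concentration-product interaction inflow */
                    if (i == 1 && j == 1)
                        d += g * y[0];
                    /* kill losses on the margins (mass moves, not copies) */
                    if (i == 0)
                        d -= kAd * y[id];
                    if (j == 0)
                        d -= kBd * y[id];
                }
                ydot[id] = d;
            }
        }
    }
}
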