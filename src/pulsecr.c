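/* Within-season derivative fields for the pulsed-reproduction
 * consumer-resource biomass model, in the form expected by deSolve's
 * compiled-model interface (initfunc + derivative functions looked up by
 * name in the package DLL).
 *
 * Parameter vector (see cr_params() on the R side):
 *   p[0] rho    resource turn-over rate
 *   p[1] Kr     maximum resource density
 *   p[2] theta  adult:juvenile mass-specific intake ratio
 *   p[3] Imax   mass-specific attack rate
 *   p[4] Q      mass-specific maintenance rate
 *   p[5] sigma  conversion efficiency
 *   p[6] mu     background mortality rate
 *   p[7] z      newborn:adult body-size ratio
 */

#include <R.h>
#include <math.h>

static double p[8];
#define RHO   p[0]
#define KR    p[1]
#define THETA p[2]
#define IMAX  p[3]
#define QM    p[4]
#define SIGMA p[5]
#define MU    p[6]
#define ZR    p[7]

void pulsecr_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, p);
}

/* Resource-dependent maturation rate gamma(nu_j, mu): zero when net
 * juvenile production is non-positive; elsewhere
 *   (nu_j - mu) / (1 - z^(1 - mu/nu_j)),
 * with the removable singularity at nu_j == mu filled by its limit
 * -nu_j / log(z).  The exponent is computed as (nu_j - mu)/nu_j (exact for
 * nearby arguments) and the denominator through expm1; inside the guard
 * band the limit carries its first-order correction, keeping the two
 * branches consistent to near machine precision. */
static double gamma_rate(double nuj, double mu, double z)
{
    if (nuj <= 0.0)
        return 0.0;
    double lz = log(z);
    double u = (nuj - mu) / nuj;
    if (fabs(nuj - mu) <= 1e-8 * mu)
        return -nuj / lz * (1.0 - 0.5 * u * lz);
    return -(nuj - mu) / expm1(u * lz);
}

static void core_rates(double R, double *nuj, double *nua, double *gam,
                       double *dj, double *da)
{
    *nuj = SIGMA * IMAX * R - QM;
    *nua = SIGMA * THETA * IMAX * R - QM;
    *gam = gamma_rate(*nuj, MU, ZR);
    *dj  = MU + (*nuj < 0.0 ? -*nuj : 0.0);  /* background + starvation */
    *da  = MU + (*nua < 0.0 ? -*nua : 0.0);
}

/* 7 states: R, J, A, B, Jbar, Abar, Bbar.  The last three accumulate the
 * season averages (integrals of J, A, B over the unit season). */
void pulsecr_season(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double nuj, nua, gam, dj, da;
    double R = y[0], J = y[1], A = y[2], B = y[3];

    core_rates(R, &nuj, &nua, &gam, &dj, &da);
    double nujp = nuj > 0.0 ? nuj : 0.0;
    double nuap = nua > 0.0 ? nua : 0.0;

    ydot[0] = RHO * (KR - R) - IMAX * R * (J + THETA * A);
    ydot[1] = nujp * J - gam * J - dj * J;
    ydot[2] = gam * J - da * A;
    ydot[3] = nuap * A - da * B;
    ydot[4] = J;
    ydot[5] = A;
    ydot[6] = B;
}

/* 12 states: the 7 above plus
 *   y[7]  S  = int_0^t (nu_j - gamma) dtau   (cohort growth excl. background
 *                                             mortality, for R0(t_m))
 *   y[8]  W  = int_0^t nu_a dtau             (storage accumulation potential)
 *   y[9]  j  \
 *   y[10] a   > unit juvenile cohort introduced at t = 0 without feedback
 *   y[11] b  /  on the resource (j(0) = 1, a(0) = b(0) = 0)
 */
void pulsecr_lifehist(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    pulsecr_season(neq, t, y, ydot, yout, ip);

    double nuj, nua, gam, dj, da;
    core_rates(y[0], &nuj, &nua, &gam, &dj, &da);
    double nujp = nuj > 0.0 ? nuj : 0.0;
    double nuap = nua > 0.0 ? nua : 0.0;
    double cj = y[9], ca = y[10], cb = y[11];

    ydot[7]  = nuj - gam;
    ydot[8]  = nua;
    ydot[9]  = nujp * cj - gam * cj - dj * cj;
    ydot[10] = gam * cj - da * ca;
    ydot[11] = nuap * ca - da * cb;
}
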