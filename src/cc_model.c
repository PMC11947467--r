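/* Compiled right-hand side of the two-population cell-cycle
 * reaction-diffusion model, in the standard deSolve compiled-model form.
 *
 * State is interleaved: y[2i] = rho1_i, y[2i+1] = rho2_i, i = 0..N-1,
 * on a uniform cell-centred grid. Diffusion is a conservative
 * finite-volume Laplacian with zero-flux boundaries; for the radial
 * geometry interior face j (between cells j-1 and j) has area r_face = j*dx
 * and cell i has volume r_i*dx with r_i = (i + 1/2)*dx.
 *
 * Parameters (via initfunc): D, k1, k2, K1, K2, kind_f, kind_g, dx, geom.
 * Crowding kinds: 0 = linear, 1 = heaviside, 2 = constant.
 * geom: 0 = cartesian1d, 1 = radial.
 */
#include <R.h>

static double parms[9];
#define P_D     parms[0]
#define P_K1RT  parms[1]
#define P_K2RT  parms[2]
#define P_KK1   parms[3]
#define P_KK2   parms[4]
#define P_KINDF parms[5]
#define P_KINDG parms[6]
#define P_DX    parms[7]
#define P_GEOM  parms[8]

void cc_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

static double crowding(int kind, double rho, double K)
{
    switch (kind) {
    case 0: { /* linear */
        double v = 1.0 - rho / K;
        return v > 0.0 ? v : 0.0;
    }
    case 1: /* heaviside, H(0) = 0: threshold density is absorbing */
        return rho < K ? 1.0 : 0.0;
    default: /* constant */
        return 1.0;
    }
}

void cc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int N = *neq / 2;
    const double dx = P_DX;
    const double inv_dx2 = 1.0 / (dx * dx);
    const int kindf = (int) P_KINDF;
    const int kindg = (int) P_KINDG;
    const int radial = (int) P_GEOM;

    for (int i = 0; i < N; i++) {
        const double rho1 = y[2 * i];
        const double rho2 = y[2 * i + 1];
        double rho = rho1 + rho2;
        if (rho < 0.0) rho = 0.0;

        double lap1, lap2;
        if (radial) {
            /* face radii j*dx and (j+1)*dx around cell i = j */
            const double rm = (double) i;        /* inner face / dx */
            const double rp = (double) (i + 1);  /* outer face / dx */
            const double ri = ((double) i + 0.5);
            double fm1 = 0.0, fm2 = 0.0, fp1 = 0.0, fp2 = 0.0;
            if (i > 0) {
                fm1 = rm * (rho1 - y[2 * (i - 1)]);
                fm2 = rm * (rho2 - y[2 * (i - 1) + 1]);
            }
            if (i < N - 1) {
                fp1 = rp * (y[2 * (i + 1)] - rho1);
                fp2 = rp * (y[2 * (i + 1) + 1] - rho2);
            }
            lap1 = (fp1 - fm1) * inv_dx2 / ri;
            lap2 = (fp2 - fm2) * inv_dx2 / ri;
        } else {
            double fm1 = 0.0, fm2 = 0.0, fp1 = 0.0, fp2 = 0.0;
            if (i > 0) {
                fm1 = rho1 - y[2 * (i - 1)];
                fm2 = rho2 - y[2 * (i - 1) + 1];
            }
            if (i < N - 1) {
                fp1 = y[2 * (i + 1)] - rho1;
                fp2 = y[2 * (i + 1) + 1] - rho2;
            }
            lap1 = (fp1 - fm1) * inv_dx2;
            lap2 = (fp2 - fm2) * inv_dx2;
        }

        const double trans = P_K1RT * crowding(kindf, rho, P_KK1) * rho1;
        const double divi  = P_K2RT * crowding(kindg, rho, P_KK2) * rho2;

        ydot[2 * i]     = P_D * lap1 - trans + 2.0 * divi;
        ydot[2 * i + 1] = P_D * lap2 + trans - divi;
    }
}
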