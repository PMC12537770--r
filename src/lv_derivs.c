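/* Three-species competitive Lotka-Volterra derivative fields for deSolve.
 *
 * State y = (N_E, N_Y, N_B) in cells/mL.  Parameter vector (length 12):
 *   0..2  r_E, r_Y, r_B        (per hour)
 *   3..5  K_E, K_Y, K_B        (cells/mL)
 *   6..11 a_EY, a_EB, a_YB, a_YE, a_BY, a_BE   (dimensionless)
 * a_ij is the effect of species j on species i.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[12];

void lvtrio_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

/* dN_i/dt = N_i r_i (1 - (N_i + sum_j a_ij N_j) / K_i) */
void lvtrio_derivs_classic(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double NE = y[0], NY = y[1], NB = y[2];
    ydot[0] = NE * parms[0] * (1.0 - (NE + parms[6] * NY + parms[7] * NB) / parms[3]);
    ydot[1] = NY * parms[1] * (1.0 - (NY + parms[8] * NB + parms[9] * NE) / parms[4]);
    ydot[2] = NB * parms[2] * (1.0 - (NB + parms[10] * NY + parms[11] * NE) / parms[5]);
}

/* Frequency-dependent variant: each interspecific term a_ij N_j is scaled by
 * the partner's relative abundance N_j / (N_E + N_Y + N_B); the self term is
 * not.  All rates are zero when the total population is zero. */
void lvtrio_derivs_freqdep(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double NE = y[0], NY = y[1], NB = y[2];
    double tot = NE + NY + NB;
    if (tot <= 0.0) {
        ydot[0] = ydot[1] = ydot[2] = 0.0;
        return;
    }
    double fE = NE / tot, fY = NY / tot, fB = NB / tot;
    ydot[0] = NE * parms[0] * (1.0 - (NE + parms[6] * fY * NY + parms[7] * fB * NB) / parms[3]);
    ydot[1] = NY * parms[1] * (1.0 - (NY + parms[8] * fB * NB + parms[9] * fE * NE) / parms[4]);
    ydot[2] = NB * parms[2] * (1.0 - (NB + parms[10] * fY * NY + parms[11] * fE * NE) / parms[5]);
}
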