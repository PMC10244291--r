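/* Compiled right-hand sides for the calcifier-alkalinity model.
 *
 * States: A (alkalinity, mol eq m^-3), P = ln(C) (log calcifiers).
 *   dA/dt = I0 * (1 + gamma(t) * S(A)) - k(t) * A * exp(P)
 *   dP/dt = k(t) * A - M
 * with the bounded weathering feedback
 *   S(A) = (2/pi) * atan( pi * (A - A0) / (2 * z0) )
 * and periodic forcing on the reaction rate
 *   k(t) = k0 * (1 + sum_i alpha_i * cos(2*pi*t/T_i + phi_i)).
 *
 * The variational system propagates a 2x2 matrix Phi alongside the base
 * trajectory: dPhi/dt = J(t) Phi, with J the analytic Jacobian of the
 * forced system (k(t) time dependent, gamma(t) from the schedule).
 *
 * Parameter vector layout (shared by both systems):
 *  [0] I0  [1] k0  [2] M  [3] A0  [4] z0
 *  [5] n_force (number of forcing components, 0..2)
 *  [6] alpha1 [7] T1 [8] phi1  [9] alpha2 [10] T2 [11] phi2
 *  [12] schedule kind (0 constant, 1 step, 2 ramp)
 *  [13] gamma1 [14] gamma2 [15] t_c [16] delta_t
 */

#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 17

static double p[N_PARMS];

void alk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

static double gamma_of_t(double t)
{
    int kind = (int) p[12];
    double g1 = p[13], g2 = p[14], tc = p[15], dt = p[16];
    if (kind == 0) return g1;
    if (kind == 1 || dt <= 0.0) return (t < tc) ? g1 : g2;
    if (t <= tc) return g1;
    if (t >= tc + dt) return g2;
    return g1 + (g2 - g1) * (t - tc) / dt;
}

static double k_of_t(double t)
{
    int nf = (int) p[5];
    double mod = 1.0;
    if (nf >= 1) mod += p[6] * cos(2.0 * M_PI * t / p[7] + p[8]);
    if (nf >= 2) mod += p[9] * cos(2.0 * M_PI * t / p[10] + p[11]);
    return p[1] * mod;
}

/* S(A) and its derivative */
static double sig(double A)
{
    return M_2_PI * atan(M_PI * (A - p[3]) / (2.0 * p[4]));
}

static double sig_prime(double A)
{
    double x = M_PI * (A - p[3]) / (2.0 * p[4]);
    return 1.0 / (p[4] * (1.0 + x * x));
}

void alk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double A = y[0], P = y[1];
    double k = k_of_t(*t);
    double g = gamma_of_t(*t);
    double C = exp(P);
    ydot[0] = p[0] * (1.0 + g * sig(A)) - k * A * C;
    ydot[1] = k * A - p[2];
    if (*ip >= 1) yout[0] = g;
}

/* base system + column-major 2x2 variational matrix:
 * y = (A, P, phi11, phi21, phi12, phi22) */
void alk_var_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double A = y[0], P = y[1];
    double k = k_of_t(*t);
    double g = gamma_of_t(*t);
    double C = exp(P);
    double j11 = p[0] * g * sig_prime(A) - k * C;
    double j12 = -k * A * C;
    double j21 = k;

    ydot[0] = p[0] * (1.0 + g * sig(A)) - k * A * C;
    ydot[1] = k * A - p[2];
    /* dPhi = J Phi, J = [[j11, j12], [j21, 0]] */
    ydot[2] = j11 * y[2] + j12 * y[3];
    ydot[3] = j21 * y[2];
    ydot[4] = j11 * y[4] + j12 * y[5];
    ydot[5] = j21 * y[4];
    /* running Liouville integral of tr(J) for the determinant check */
    ydot[6] = j11;
    if (*ip >= 1) yout[0] = g;
}

static const R_CMethodDef cMethods[] = {
    {"alk_initmod",    (DL_FUNC) &alk_initmod,    1},
    {"alk_derivs",     (DL_FUNC) &alk_derivs,     6},
    {"alk_var_derivs", (DL_FUNC) &alk_var_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_alkcycle(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
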