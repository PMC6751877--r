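/* Compiled right-hand sides for the three gene-circuit ODE models,
 * in the deSolve compiled-model calling convention.
 *
 * Parameter vectors are passed via the initfunc mechanism; the order is
 * fixed and mirrored by the R-side model definitions:
 *   repressilator: alpha, alpha0, n, beta, delta_m, delta_p, Kd
 *   acdc:          alpha, n, beta, delta_m, delta_p, Kd_a, Kd_b, Kd_c, Kd_d
 *   dflipflop:     alpha1, alpha2, alpha3, alpha4, delta1, delta2, Kd, n,
 *                  K_M, E_prot, delta_dil, omega1, omega2,
 *                  clk_period, clk_amplitude, clk_duty, d_mode, d_value
 *
 * States: repressilator/acdc mX, mY, mZ, X, Y, Z; flip-flop a, a_c, q, q_c.
 * Concentrations in nM, time in h. Solver excursions below 0 are clamped
 * to 0 inside Hill terms only (the state itself is left to the solver).
 */

#include <R.h>
#include <math.h>

static double p_rep[7];
static double p_acdc[9];
static double p_ff[18];

void viaspace_init_rep(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, p_rep);
}

void viaspace_init_acdc(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, p_acdc);
}

void viaspace_init_ff(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, p_ff);
}

static double hillr(double x, double Kd, double n)
{
    /* (x/Kd)^n with negative solver excursions treated as 0 */
    if (x <= 0.0) return 0.0;
    return pow(x / Kd, n);
}

double viaspace_clk(double t, double period, double amplitude, double duty)
{
    double phase = fmod(t, period);
    if (phase < 0) phase += period;
    return (phase < duty * period) ? amplitude : 0.0;
}

void viaspace_deriv_rep(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    const double alpha = p_rep[0], alpha0 = p_rep[1], n = p_rep[2],
                 beta = p_rep[3], delta_m = p_rep[4], delta_p = p_rep[5],
                 Kd = p_rep[6];
    const double mX = y[0], mY = y[1], mZ = y[2], X = y[3], Y = y[4], Z = y[5];
    ydot[0] = -delta_m * mX + alpha / (1.0 + hillr(Z, Kd, n)) + alpha0;
    ydot[1] = -delta_m * mY + alpha / (1.0 + hillr(X, Kd, n)) + alpha0;
    ydot[2] = -delta_m * mZ + alpha / (1.0 + hillr(Y, Kd, n)) + alpha0;
    ydot[3] = beta * mX - delta_p * X;
    ydot[4] = beta * mY - delta_p * Y;
    ydot[5] = beta * mZ - delta_p * Z;
}

void viaspace_deriv_acdc(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    const double alpha = p_acdc[0], n = p_acdc[1], beta = p_acdc[2],
                 delta_m = p_acdc[3], delta_p = p_acdc[4], Kd_a = p_acdc[5],
                 Kd_b = p_acdc[6], Kd_c = p_acdc[7], Kd_d = p_acdc[8];
    const double mX = y[0], mY = y[1], mZ = y[2], X = y[3], Y = y[4], Z = y[5];
    ydot[0] = -delta_m * mX + alpha / (1.0 + hillr(Z, Kd_a, n) + hillr(Y, Kd_b, n));
    ydot[1] = -delta_m * mY + alpha / (1.0 + hillr(X, Kd_c, n));
    ydot[2] = -delta_m * mZ + alpha / (1.0 + hillr(Y, Kd_d, n));
    ydot[3] = beta * mX - delta_p * X;
    ydot[4] = beta * mY - delta_p * Y;
    ydot[5] = beta * mZ - delta_p * Z;
}

void viaspace_deriv_ff(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double alpha1 = p_ff[0], alpha2 = p_ff[1], alpha3 = p_ff[2],
                 alpha4 = p_ff[3], delta1 = p_ff[4], delta2 = p_ff[5],
                 Kd = p_ff[6], n = p_ff[7], K_M = p_ff[8], E_prot = p_ff[9],
                 delta_dil = p_ff[10], omega1 = p_ff[11], omega2 = p_ff[12],
                 clk_period = p_ff[13], clk_amplitude = p_ff[14],
                 clk_duty = p_ff[15], d_mode = p_ff[16], d_value = p_ff[17];
    const double a = y[0], a_c = y[1], q = y[2], q_c = y[3];
    const double CLK = viaspace_clk(*t, clk_period, clk_amplitude, clk_duty);
    /* counter mode wires the input to the inverted slave output */
    const double d = (d_mode == 0.0) ? q_c : d_value;

    const double hd = hillr(d, Kd, n), hc = hillr(CLK, Kd, n);
    const double ha = hillr(a, Kd, n), hac = hillr(a_c, Kd, n);
    const double hq = hillr(q, Kd, n), hqc = hillr(q_c, Kd, n);
    const double den_m = 1.0 + hd + hc + omega1 * hd * hc;

    const double P = a + a_c + q + q_c;
    const double f1 = (omega2 == 0.0)
        ? delta1 * E_prot / (K_M + P) + delta_dil : delta1;
    const double f2 = (omega2 == 0.0)
        ? delta2 * E_prot / (K_M + P) + delta_dil : delta2;

    ydot[0] = alpha1 * hd / den_m + alpha2 / (1.0 + hac) - a * f1;
    ydot[1] = alpha1 / den_m + alpha2 / (1.0 + ha) - a_c * f1;
    ydot[2] = alpha3 * ha * hc / (1.0 + ha + hc + ha * hc)
        + alpha4 / (1.0 + hqc) - q * f2;
    ydot[3] = alpha3 * hac * hc / (1.0 + hac + hc + hac * hc)
        + alpha4 / (1.0 + hq) - q_c * f2;
}
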