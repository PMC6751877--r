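/* Gillespie direct-method kernels for the built-in circuits.
 *
 * The deterministic rate laws are projected directly onto stochastic
 * propensities (QSSA projection): one production and one degradation
 * channel per species, with Hill/Michaelis-Menten terms evaluated at the
 * current copy numbers. With the reaction volume factor V_R*N_A = 1 nM^-1,
 * 1 molecule corresponds to 1 nM; an optional scale factor `omega`
 * multiplies copy numbers (propensity a(x) = omega * a_det(x / omega)),
 * which is used to probe the mean-field (large copy number) limit.
 *
 * The flip-flop CLK input is a deterministic square wave: propensities are
 * piecewise constant in time, so the direct method stays exact as long as
 * waiting times are truncated at the next CLK edge.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>

double viaspace_clk(double t, double period, double amplitude, double duty);

static double hillp(double x, double Kd, double n)
{
    if (x <= 0.0) return 0.0;
    return pow(x / Kd, n);
}

/* propensities; x holds copy numbers, conc = x / omega */
static void prop_rep(const double *x, const double *p, double om, double t,
                     double *a)
{
    const double alpha = p[0], alpha0 = p[1], n = p[2], beta = p[3],
                 delta_m = p[4], delta_p = p[5], Kd = p[6];
    a[0] = om * (alpha / (1.0 + hillp(x[5] / om, Kd, n)) + alpha0);
    a[1] = om * (alpha / (1.0 + hillp(x[3] / om, Kd, n)) + alpha0);
    a[2] = om * (alpha / (1.0 + hillp(x[4] / om, Kd, n)) + alpha0);
    a[3] = delta_m * x[0];
    a[4] = delta_m * x[1];
    a[5] = delta_m * x[2];
    a[6] = beta * x[0];
    a[7] = beta * x[1];
    a[8] = beta * x[2];
    a[9] = delta_p * x[3];
    a[10] = delta_p * x[4];
    a[11] = delta_p * x[5];
}

static void prop_acdc(const double *x, const double *p, double om, double t,
                      double *a)
{
    const double alpha = p[0], n = p[1], beta = p[2], delta_m = p[3],
                 delta_p = p[4], Kd_a = p[5], Kd_b = p[6], Kd_c = p[7],
                 Kd_d = p[8];
    a[0] = om * alpha / (1.0 + hillp(x[5] / om, Kd_a, n) + hillp(x[4] / om, Kd_b, n));
    a[1] = om * alpha / (1.0 + hillp(x[3] / om, Kd_c, n));
    a[2] = om * alpha / (1.0 + hillp(x[4] / om, Kd_d, n));
    a[3] = delta_m * x[0];
    a[4] = delta_m * x[1];
    a[5] = delta_m * x[2];
    a[6] = beta * x[0];
    a[7] = beta * x[1];
    a[8] = beta * x[2];
    a[9] = delta_p * x[3];
    a[10] = delta_p * x[4];
    a[11] = delta_p * x[5];
}

static void prop_ff(const double *x, const double *p, double om, double t,
                    double *a)
{
    const double alpha1 = p[0], alpha2 = p[1], alpha3 = p[2], alpha4 = p[3],
                 delta1 = p[4], delta2 = p[5], Kd = p[6], n = p[7],
                 K_M = p[8], E_prot = p[9], delta_dil = p[10],
                 omega1 = p[11], omega2 = p[12];
    const double CLK = viaspace_clk(t, p[13], p[14], p[15]);
    const double ca = x[0] / om, cac = x[1] / om, cq = x[2] / om,
                 cqc = x[3] / om;
    const double d = (p[16] == 0.0) ? cqc : p[17];
    const double hd = hillp(d, Kd, n), hc = hillp(CLK, Kd, n);
    const double ha = hillp(ca, Kd, n), hac = hillp(cac, Kd, n);
    const double hq = hillp(cq, Kd, n), hqc = hillp(cqc, Kd, n);
    const double den_m = 1.0 + hd + hc + omega1 * hd * hc;
    const double P = ca + cac + cq + cqc;
    const double f1 = (omega2 == 0.0)
        ? delta1 * E_prot / (K_M + P) + delta_dil : delta1;
    const double f2 = (omega2 == 0.0)
        ? delta2 * E_prot / (K_M + P) + delta_dil : delta2;

    a[0] = om * (alpha1 * hd / den_m + alpha2 / (1.0 + hac));
    a[1] = om * (alpha1 / den_m + alpha2 / (1.0 + ha));
    a[2] = om * (alpha3 * ha * hc / (1.0 + ha + hc + ha * hc)
                 + alpha4 / (1.0 + hqc));
    a[3] = om * (alpha3 * hac * hc / (1.0 + hac + hc + hac * hc)
                 + alpha4 / (1.0 + hq));
    a[4] = f1 * x[0];
    a[5] = f1 * x[1];
    a[6] = f2 * x[2];
    a[7] = f2 * x[3];
}

/* +1 / -1 single-species stoichiometry: reaction r changes species
 * spc[r] by sgn[r] */
static const int rep_spc[12] = {0, 1, 2, 0, 1, 2, 3, 4, 5, 3, 4, 5};
static const int rep_sgn[12] = {1, 1, 1, -1, -1, -1, 1, 1, 1, -1, -1, -1};
static const int ff_spc[8] = {0, 1, 2, 3, 0, 1, 2, 3};
static const int ff_sgn[8] = {1, 1, 1, 1, -1, -1, -1, -1};

SEXP viaspace_ssa_run(SEXP s_model, SEXP s_parms, SEXP s_y0, SEXP s_times,
                      SEXP s_scale)
{
    const int model = INTEGER(s_model)[0]; /* 1 rep, 2 acdc, 3 flip-flop */
    const double *parms = REAL(s_parms);
    const double om = REAL(s_scale)[0];
    const int nt = LENGTH(s_times);
    const double *times = REAL(s_times);
    const int ns = (model == 3) ? 4 : 6;
    const int nr = (model == 3) ? 8 : 12;
    const int *spc = (model == 3) ? ff_spc : rep_spc;
    const int *sgn = (model == 3) ? ff_sgn : rep_sgn;
    void (*prop)(const double *, const double *, double, double, double *) =
        (model == 1) ? prop_rep : (model == 2) ? prop_acdc : prop_ff;

    double x[6], a[12];
    for (int i = 0; i < ns; i++) x[i] = REAL(s_y0)[i];

    SEXP s_out = PROTECT(allocMatrix(REALSXP, nt, ns));
    double *out = REAL(s_out);

    /* CLK edge times (flip-flop only): propensities are constant between
     * consecutive edges, so cap each waiting time at the next edge */
    const double period = (model == 3) ? parms[13] : 0.0;
    const double duty = (model == 3) ? parms[15] : 0.5;

    GetRNGstate();
    double t = times[0];
    int iout = 0;
    const double tend = times[nt - 1];
    long long maxevents = 200000000LL; /* hard safety cap */

    while (iout < nt) {
        double tnext;
        prop(x, parms, om, t, a);
        double a0 = 0.0;
        for (int r = 0; r < nr; r++) a0 += a[r];

        double tedge = R_PosInf;
        if (model == 3) {
            double ph = fmod(t, period);
            if (ph < 0) ph += period;
            double rem = (ph < duty * period) ? duty * period - ph
                                              : period - ph;
            tedge = t + rem + 1e-12;
        }

        if (a0 <= 0.0 || !R_FINITE(a0)) {
            tnext = (tedge < tend) ? tedge : tend + 1.0;
            if (!R_FINITE(a0)) { /* propensity overflow: freeze state */
                tnext = tend + 1.0;
            }
            while (iout < nt && times[iout] <= tnext) {
                for (int i = 0; i < ns; i++) out[iout + nt * i] = x[i];
                iout++;
            }
            t = tnext;
            if (t > tend) break;
            continue;
        }

        double tau = exp_rand() / a0;
        tnext = t + tau;
        if (tnext > tedge) { /* cross a CLK edge without reacting */
            while (iout < nt && times[iout] <= tedge) {
                for (int i = 0; i < ns; i++) out[iout + nt * i] = x[i];
                iout++;
            }
            t = tedge;
            continue;
        }
        /* record outputs strictly before the event time */
        while (iout < nt && times[iout] < tnext) {
            for (int i = 0; i < ns; i++) out[iout + nt * i] = x[i];
            iout++;
        }
        if (tnext > tend) break;
        t = tnext;
        double u = unif_rand() * a0, c = 0.0;
        int r = nr - 1;
        for (int k = 0; k < nr; k++) {
            c += a[k];
            if (u <= c) { r = k; break; }
        }
        x[spc[r]] += sgn[r];
        if (x[spc[r]] < 0) x[spc[r]] = 0;
        if (--maxevents <= 0) {
            warning("SSA event cap reached; trajectory truncated");
            break;
        }
    }
    /* fill any remaining grid points with the final state */
    while (iout < nt) {
        for (int i = 0; i < ns; i++) out[iout + nt * i] = x[i];
        iout++;
    }
    PutRNGstate();
    UNPROTECT(1);
    return s_out;
}
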