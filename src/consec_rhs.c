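/* Right-hand side of the consecutive three-step decomposition scheme
 * A -> B -> C -> D with Sestak-Berggren rate functions, in the form
 * consumed by deSolve's compiled-function interface.
 *
 * Parameter vector layout (0-based):
 *   [0]        number of program segments (<= 4)
 *   [1..16]    per segment: t0, t1, T_start, rate (rate 0 => hold)
 *   [17..40]   per step (3 x 8): mode, E0|b, c, Tmin, Tmax, A, M, N
 *              mode 0: constant E = E0 (J/mol)
 *              mode 1: E(T) = -R*(b + 2*c/T), T clamped to [Tmin, Tmax]
 *   [41]       conversion mode: 0 product-species amounts, 1 step conversions
 */
#include <R.h>
#include <math.h>

#define RGAS 8.314
#define NPARMS 42

static double parms[NPARMS];

void initmod_consec(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double program_T(double t)
{
    int nseg = (int) parms[0];
    int i;
    /* clamp to program bounds; the solver may probe marginally outside */
    if (t <= parms[1]) t = parms[1];
    for (i = 0; i < nseg; i++) {
        double t0 = parms[1 + 4 * i], t1 = parms[2 + 4 * i];
        if (t <= t1 || i == nseg - 1) {
            double T0 = parms[3 + 4 * i], rate = parms[4 + 4 * i];
            double tl = t - t0;
            if (tl < 0) tl = 0;
            if (tl > t1 - t0) tl = t1 - t0;
            return T0 + rate * tl;
        }
    }
    return parms[3]; /* unreachable */
}

static double sb(double a, double M, double N)
{
    if (a < 0) a = 0;
    if (a > 1) a = 1;
    /* pow(0,0) == 1 by C99, matching the M == 0 first-order limit */
    return pow(a, M) * pow(1 - a, N);
}

/* Smooth (C1) source-availability gate: a step's rate falls to zero as its
 * source species is exhausted, keeping all occupations in [0, 1] and the
 * right-hand side Lipschitz in the supply-limited regime. */
static double gate(double m_src)
{
    double g = m_src / 1e-6;
    if (g < 0) return 0;
    if (g > 1) return 1;
    return g * g * (3 - 2 * g);
}

static double step_k(int j, double T)
{
    const double *sp = parms + 17 + 8 * j;
    double E;
    if (sp[0] < 0.5) {
        E = sp[1];
    } else {
        double Tc = T;
        if (Tc < sp[3]) Tc = sp[3];
        if (Tc > sp[4]) Tc = sp[4];
        E = -RGAS * (sp[1] + 2 * sp[2] / Tc);
    }
    return sp[5] * exp(-E / (RGAS * T));
}

void derivs_consec(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double T = program_T(*t);
    double mA = y[0], mB = y[1], mC = y[2];
    double mD, a1, a2, a3, r1, r2, r3;

    /* solver iterates may stray to tiny negative values; evaluate the rate
     * law on the physical simplex */
    if (mA < 0) mA = 0; if (mA > 1) mA = 1;
    if (mB < 0) mB = 0; if (mB > 1) mB = 1;
    if (mC < 0) mC = 0; if (mC > 1) mC = 1;
    mD = 1 - mA - mB - mC;
    if (mD < 0) mD = 0;

    if (parms[41] < 0.5) {
        a1 = mB; a2 = mC; a3 = mD;
    } else {
        a1 = 1 - mA;
        a2 = (mC + mD) / (1 - mA + 1e-9);
        a3 = mD / (mC + mD + 1e-9);
    }
    /* each rate is gated on its source species: in the product convention
     * this is what stops a step when its source runs out; in the step
     * convention it regularises the supply-limited regime, where
     * (1-alpha)^N with N < 1 is otherwise non-Lipschitz in the source */
    r1 = gate(mA) * step_k(0, T) * sb(a1, parms[17 + 6], parms[17 + 7]);
    r2 = gate(mB) * step_k(1, T) * sb(a2, parms[25 + 6], parms[25 + 7]);
    r3 = gate(mC) * step_k(2, T) * sb(a3, parms[33 + 6], parms[33 + 7]);

    ydot[0] = -r1;
    ydot[1] = r1 - r2;
    ydot[2] = r2 - r3;
}
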