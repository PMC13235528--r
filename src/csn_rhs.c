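/* Compiled right-hand side of the assembled network ODE system, for use
 * with deSolve's compiled-function interface.  Mirrors the reference R
 * implementation in R/currents.R, R/synapses.R and R/network.R; the two
 * are cross-checked in the test suite.
 *
 * Parameter vector layout (doubles, padded to PARMS_LEN):
 *   [0] n_neurons  [1] n_synapses  [2] n_pulses  [3] reserved
 *   then per neuron, a block of NEUPAR values:
 *     [0] class flag (1 = HVC_X with calcium pool, 0 = HVC_INT)
 *     [1] 0-based offset of the neuron's states in y
 *     [2..50] the 49 canonical neuron parameters (see R/params.R)
 *   then per synapse, a block of SYNPAR values:
 *     pre index, post index, g, Vrev, ar, ad, Tmax, Kp, VT, state index
 *   then per stimulus pulse, a block of 4 values:
 *     target neuron index, onset, duration, amplitude
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define PARMS_LEN 4096
#define HDR 4
#define NEUPAR 52
#define SYNPAR 10
#define PULPAR 4
#define MAX_NEU 32
#define MAX_SYN 96

static double parms[PARMS_LEN];

void csn_initmod(void (*odeparms)(int *, double *))
{
    int N = PARMS_LEN;
    odeparms(&N, parms);
}

static double sig(double V, double theta, double sigma)
{
    return 1.0 / (1.0 + exp((V - theta) / sigma));
}

static double ghk(double V, double Caex, double k)
{
    double x = k * V;
    if (fabs(x) < 1e-4) {
        return -Caex / k * (1.0 - x / 2.0 + x * x / 12.0
                            - x * x * x * x / 720.0);
    }
    return Caex * V / (1.0 - exp(x));
}

void csn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int n_neu = (int) parms[0];
    const int n_syn = (int) parms[1];
    const int n_pul = (int) parms[2];
    const double *np = parms + HDR;
    const double *sp = np + n_neu * NEUPAR;
    const double *pp = sp + n_syn * SYNPAR;
    double Vpre[MAX_NEU], Isyn[MAX_NEU];
    int i, k;

    for (i = 0; i < n_neu; i++) {
        const double *b = np + i * NEUPAR;
        Vpre[i] = y[(int) b[1]];
        Isyn[i] = 0.0;
    }

    /* synapses: gate ODEs and postsynaptic currents */
    for (k = 0; k < n_syn; k++) {
        const double *s = sp + k * SYNPAR;
        int pre = (int) s[0], post = (int) s[1];
        double g = s[2], Vrev = s[3], ar = s[4], ad = s[5];
        double Tmax = s[6], Kp = s[7], VT = s[8];
        int idx = (int) s[9];
        double sv = y[idx];
        double T = Tmax / (1.0 + exp(-(Vpre[pre] - VT) / Kp));
        ydot[idx] = ar * T * (1.0 - sv) - ad * sv;
        Isyn[post] += g * sv * (Vpre[post] - Vrev);
    }

    for (i = 0; i < n_neu; i++) {
        const double *b = np + i * NEUPAR;
        const double *q = b + 2;
        int is_x = (int) b[0];
        int off = (int) b[1];
        double V = y[off], n = y[off + 1], h = y[off + 2], e = y[off + 3];
        double rT = y[off + 4], rf = y[off + 5], rs = y[off + 6];
        double Cm = q[0];
        double gNa = q[1], gK = q[2], gA = q[3], gL = q[4], gCaL = q[5];
        double gCaT = q[6], gSK = q[7], gH = q[8];
        double VNa = q[9], VK = q[10], VL = q[11], Vh = q[12];
        double drive = ghk(V, q[47], q[48]);

        double IL = gL * (V - VL);
        double IK = gK * n * n * n * n * (V - VK);
        double minf = sig(V, q[13], q[14]);
        double INa = gNa * minf * minf * minf * h * (V - VNa);
        double IA = gA * sig(V, q[21], q[22]) * e * (V - VK);
        double sinf = sig(V, q[23], q[24]);
        double ICaL = gCaL * sinf * sinf * drive;
        double aT = sig(V, q[25], q[26]);
        double bT = sig(rT, q[27], q[28]) - sig(0.0, q[27], q[28]);
        double ICaT = gCaT * aT * aT * aT * bT * bT * bT * drive;
        double IH = gH * (q[35] * rf + (1.0 - q[35]) * rs) * (V - Vh);
        double ISK = 0.0;
        if (is_x) {
            double Ca = y[off + 7];
            double ks = q[46];
            ISK = gSK * Ca * Ca / (Ca * Ca + ks * ks) * (V - VK);
        }

        /* applied current: sum of active DC pulses, half-open windows */
        double Iapp = 0.0;
        for (k = 0; k < n_pul; k++) {
            const double *pu = pp + k * PULPAR;
            if ((int) pu[0] == i && *t >= pu[1] && *t < pu[1] + pu[2])
                Iapp += pu[3];
        }

        ydot[off] = (-(IL + IK + INa + IA + ICaL + ICaT + ISK + IH)
                     - Isyn[i] + Iapp) / Cm;

        /* gate kinetics */
        double ah = 0.128 * exp(-(V + 15.0) / 18.0);
        double bh = 4.0 / (1.0 + exp(-(V + 27.0) / 5.0));
        ydot[off + 1] = (sig(V, q[15], q[16]) - n) / q[17];
        ydot[off + 2] = ah * (1.0 - h) - bh * h;
        ydot[off + 3] = (sig(V, q[18], q[19]) - e) / q[20];
        double tau_rT = q[31] + q[32] * sig(V, q[33], q[34]);
        ydot[off + 4] = (sig(V, q[29], q[30]) - rT) / tau_rT;
        double u = V + 70.0;
        double lin = (fabs(u) < 1e-6) ? 7.4 * 0.8
            : -7.4 * u / (exp(u / -0.8) - 1.0);
        double tau_rf = q[36] * (lin + 65.0 * exp((V + 56.0) / -23.0));
        ydot[off + 5] = (sig(V, q[37], q[38]) - rf) / tau_rf;
        double rsinf = 1.0 / (1.0 + exp(-(V - q[39]) / q[40]));
        ydot[off + 6] = (rsinf - rs) / q[41];
        if (is_x) {
            double Ca = y[off + 7];
            ydot[off + 7] = -q[42] * q[43] * (ICaL + ICaT)
                - q[44] * (Ca - q[45]);
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"csn_initmod", (DL_FUNC) &csn_initmod, 1},
    {"csn_derivs", (DL_FUNC) &csn_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_csnsim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
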