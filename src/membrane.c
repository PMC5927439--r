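/* Right-hand side of the electrocyte posterior-membrane model for deSolve.
 *
 * State: y = (V [mV], m, h, n).  Conductance currents are in nA (uS * mV);
 * the AChR synaptic currents are evaluated with the Goldman-Hodgkin-Katz
 * flux equation in SI units and converted to nA.  Sign convention:
 * conductance and GHK currents are positive outward; injected clamp
 * current is positive depolarizing.
 */
#include <R.h>
#include <math.h>

/* parameter vector layout; must match .epm_c_parms() on the R side */
#define N_PARMS 43
#define P_CAP    0
#define P_GNA    1
#define P_GK     2
#define P_GL     3
#define P_GAMMA  4
#define P_ENA    5
#define P_EK     6
#define P_EL     7
#define P_KAM    8
#define P_EAM    9
#define P_KBM   10
#define P_EBM   11
#define P_KAH   12
#define P_EAH   13
#define P_BHMAX 14
#define P_BHV0  15
#define P_BHK   16
#define P_KAN   17
#define P_EAN   18
#define P_KBN   19
#define P_EBN   20
#define P_PNA   21  /* m^3/s */
#define P_PK    22  /* m^3/s */
#define P_NAI   23  /* mol/m^3 */
#define P_NAO   24
#define P_KI    25
#define P_KO    26
#define P_RTF   27  /* RT/F in mV */
#define P_FARAD 28  /* C/mol */
/* stimulus description */
#define P_BG    29  /* background syn_clamp level */
#define P_PAMP  30  /* pulsatile amplitude */
#define P_PFREQ 31  /* Hz */
#define P_PRISE 32  /* ms */
#define P_PPLAT 33  /* ms */
#define P_PTAU  34  /* ms */
#define P_SYNT0 35  /* ms */
#define P_SYNDUR 36 /* ms */
#define P_CKIND 37  /* 0 none, 1 step, 2 ramp, 3 pulse train */
#define P_CAMP  38  /* nA (ramp: peak) */
#define P_CT0   39
#define P_CDUR  40
#define P_CWID  41  /* ms, pulse-train width */
#define P_CFREQ 42  /* Hz, pulse-train rate */

static double parms[N_PARMS];

void epm_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* u/(1 - exp(-u)) with a 4-term Taylor expansion near the removable
 * singularity at u = 0 */
static double ghk_ufac(double u)
{
    if (fabs(u) < 1e-4)
        return 1.0 + u / 2.0 + u * u / 12.0 - u * u * u * u / 720.0;
    return u / (1.0 - exp(-u));
}

/* single-ion GHK current, outward positive, in nA (z = +1) */
static double ghk_nA(double v, double cin, double cout, double perm)
{
    double u = v / parms[P_RTF];
    return perm * parms[P_FARAD] * ghk_ufac(u) * (cin - cout * exp(-u)) * 1e9;
}

/* unit pulsatile waveform: linear rise, plateau, exponential decay,
 * restarted each period */
static double pulse_unit(double s)
{
    if (s < parms[P_PRISE])
        return s / parms[P_PRISE];
    if (s < parms[P_PRISE] + parms[P_PPLAT])
        return 1.0;
    return exp(-(s - parms[P_PRISE] - parms[P_PPLAT]) / parms[P_PTAU]);
}

static double syn_level_at(double t)
{
    double lev = 0.0;
    if (t < parms[P_SYNT0] || t > parms[P_SYNT0] + parms[P_SYNDUR])
        return 0.0;
    lev = parms[P_BG];
    if (parms[P_PAMP] > 0.0 && parms[P_PFREQ] > 0.0) {
        double per = 1000.0 / parms[P_PFREQ];
        double s = fmod(t - parms[P_SYNT0], per);
        lev += parms[P_PAMP] * pulse_unit(s);
    }
    return lev;
}

static double clamp_at(double t)
{
    int kind = (int) parms[P_CKIND];
    double tr = t - parms[P_CT0];
    if (kind == 0 || tr < 0.0 || tr > parms[P_CDUR])
        return 0.0;
    if (kind == 1)                       /* step */
        return parms[P_CAMP];
    if (kind == 2)                       /* ramp to peak */
        return parms[P_CAMP] * tr / parms[P_CDUR];
    if (kind == 3) {                     /* rectangular pulse train */
        double per = 1000.0 / parms[P_CFREQ];
        return (fmod(tr, per) < parms[P_CWID]) ? parms[P_CAMP] : 0.0;
    }
    return 0.0;
}

void epm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double v = y[0], m = y[1], h = y[2], n = y[3];
    double am, bm, ah, bh, an, bn;
    double m3 = m * m * m, n4 = n * n * n * n;
    double i_na_t, i_na_p, i_k, i_leak, g_na, g_k;
    double syn, i_ach_na, i_ach_k, i_clamp;

    am = parms[P_KAM] * exp(parms[P_EAM] * v);
    bm = parms[P_KBM] * exp(parms[P_EBM] * v);
    ah = parms[P_KAH] * exp(parms[P_EAH] * v);
    bh = parms[P_BHMAX] / (exp(-(v - parms[P_BHV0]) / parms[P_BHK]) + 1.0);
    an = parms[P_KAN] * exp(parms[P_EAN] * v);
    bn = parms[P_KBN] * exp(parms[P_EBN] * v);

    g_na = parms[P_GNA] * m3;
    g_k  = parms[P_GK] * n4;
    i_na_t = g_na * h * (1.0 - parms[P_GAMMA]) * (v - parms[P_ENA]);
    i_na_p = g_na * parms[P_GAMMA] * (v - parms[P_ENA]);
    i_k    = g_k * (v - parms[P_EK]);
    i_leak = parms[P_GL] * (v - parms[P_EL]);

    syn = syn_level_at(*t);
    i_ach_na = syn * ghk_nA(v, parms[P_NAI], parms[P_NAO], parms[P_PNA]);
    i_ach_k  = syn * ghk_nA(v, parms[P_KI], parms[P_KO], parms[P_PK]);
    i_clamp  = clamp_at(*t);

    ydot[0] = (-(i_na_t + i_na_p + i_k + i_leak)
               - (i_ach_na + i_ach_k) + i_clamp) / parms[P_CAP];
    ydot[1] = am * (1.0 - m) - bm * m;
    ydot[2] = ah * (1.0 - h) - bh * h;
    ydot[3] = an * (1.0 - n) - bn * n;

    if (ip[0] >= 8) {
        yout[0] = i_na_t;
        yout[1] = i_na_p;
        yout[2] = i_k;
        yout[3] = i_leak;
        yout[4] = i_ach_na;
        yout[5] = i_ach_k;
        yout[6] = i_clamp;
        yout[7] = syn;
    }
}
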