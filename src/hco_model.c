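/* Conductance-based half-center oscillator vector field.
 *
 * Two identical, mutually inhibitory Hodgkin-Huxley neurons, each with
 * 11 state variables:
 *   y[0]  Vm    membrane potential (mV)
 *   y[1]  hNaF  fast Na+ inactivation
 *   y[2]  mNaP  persistent Na+ activation
 *   y[3]  hNaP  persistent Na+ inactivation
 *   y[4]  mKDR  delayed-rectifier K+ activation
 *   y[5]  hKA   A-type K+ inactivation
 *   y[6]  mCaS  slow Ca2+ activation
 *   y[7]  hCaS  slow Ca2+ inactivation
 *   y[8]  mh    h-current activation (the leading slow variable)
 *   y[9]  mSyn  synaptic release variable (drives the OTHER cell)
 *   y[10] Nai   intracellular Na+ concentration (mM)
 *
 * Units: mV, s, nS, pA, nF, mM (nS*mV = pA; pA/nF = mV/s).
 * All ionic currents are positive-outward; the conservation equation is
 * C dV/dt = -(sum of currents).
 *
 * Registered with deSolve as dllname = "hcorhythm", initfunc = "hco_init",
 * func = "hco_derivs".  The parameter vector layout must match
 * .hcoParmVector() on the R side exactly.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 37

static double parms[N_PARMS];

/* parameter slots (keep in sync with .hcoParmVector in R/simulate.R) */
#define p_C           parms[0]
#define p_gNaF        parms[1]
#define p_gNaP        parms[2]
#define p_gKDR        parms[3]
#define p_gKA         parms[4]
#define p_gh          parms[5]
#define p_gCaS        parms[6]
#define p_gSyn        parms[7]
#define p_ECa         parms[8]
#define p_ESyn        parms[9]
#define p_IPumpMax    parms[10]
#define p_Nae         parms[11]
#define p_M           parms[12]
#define p_alpha       parms[13]
#define p_tauh_scale  parms[14]
#define p_RTF         parms[15]
#define p_EK          parms[16]  /* precomputed Nernst EK (fixed K+) */
#define p_gLNa        parms[17]  /* precomputed leak split */
#define p_gLK         parms[18]
#define p_Kfac        parms[19]  /* precomputed pump K+ activation factor */
/* kinetics constants that are exposed for the ambiguous printed forms */
#define p_mh_k1       parms[20]
#define p_mh_k2       parms[21]
#define p_mh_vhalf    parms[22]
#define p_tauh_base   parms[23]
#define p_tauh_amp    parms[24]
#define p_tauh_slope  parms[25]
#define p_tauh_vhalf  parms[26]
#define p_hNaF_slope  parms[27]
#define p_hNaF_vhalf  parms[28]
#define p_thNaF_s1    parms[29]
#define p_thNaF_s2    parms[30]
#define p_thKDR_s1    parms[31]
#define p_thKDR_s2    parms[32]
#define p_tCaS_scale  parms[33]
#define p_tCaS_mode   parms[34]  /* 0 = alpha/beta rates, 1 = sigmoid sum */
/* run-mode switches */
#define p_ncell       parms[35]  /* 1 = decoupled single cell, 2 = HCO */
#define p_mh_frozen   parms[36]  /* 1 = reduced constant-m_h model */

void hco_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* Boltzmann f_inf(a, vhalf, v) = 1/(1 + exp((v - vhalf)/a));
 * a < 0 gives activation (increasing in v), a > 0 inactivation. */
static R_INLINE double finf(double a, double vhalf, double v)
{
    return 1.0 / (1.0 + exp((v - vhalf) / a));
}

static void cell_derivs(const double *y, double mSynPre, double *dy)
{
    const double V    = y[0];
    const double hNaF = y[1], mNaP = y[2], hNaP = y[3], mKDR = y[4];
    const double hKA  = y[5], mCaS = y[6], hCaS = y[7], mh = y[8];
    const double mSyn = y[9], Nai = y[10];

    const double ENa = p_RTF * log(p_Nae / Nai);
    const double EK  = p_EK;

    /* instantaneous activations */
    const double mNaF = finf(-7.8, -15.0, V);
    const double mKA  = finf(-10.0, -20.0, V);

    const double INaF = p_gNaF * mNaF * mNaF * mNaF * hNaF * (V - ENa);
    const double INaP = p_gNaP * mNaP * hNaP * (V - ENa);
    const double mKDR2 = mKDR * mKDR;
    const double IKDR = p_gKDR * mKDR2 * mKDR2 * (V - EK);
    const double IKA  = p_gKA * mKA * hKA * (V - EK);
    const double mh2  = mh * mh;
    const double IhNa = (3.0 / 7.0) * p_gh * mh2 * (V - ENa);
    const double IhK  = (4.0 / 7.0) * p_gh * mh2 * (V - EK);
    const double ICaS = p_gCaS * mCaS * mCaS * mCaS * hCaS * (V - p_ECa);
    const double ILNa = p_gLNa * (V - ENa);
    const double ILK  = p_gLK * (V - EK);
    const double IPump = p_IPumpMax * p_Kfac / (1.0 + exp((25.0 - Nai) / 3.0));
    const double ISyn = p_gSyn * mSynPre * (V - p_ESyn);

    dy[0] = -(INaF + INaP + IKDR + IKA + IhNa + IhK + ICaS +
              ILNa + ILK + IPump + ISyn) / p_C;

    /* voltage-dependent time constants (s) */
    const double x43 = V + 43.0;
    const double tau_hNaF = 0.03 /
        (exp(x43 / p_thNaF_s1) + exp(x43 / p_thNaF_s2));
    const double tau_mKDR = 0.007 /
        (exp(x43 / p_thKDR_s1) + exp(x43 / p_thKDR_s2));

    const double x1 = V + 48.01, x2 = V + 51.01;
    double tau_mCaS;
    if (p_tCaS_mode < 0.5) {
        /* alpha/beta rate form; x/(1-exp(-x/s)) -> s as x -> 0 */
        const double A = (fabs(x1) < 1e-7) ? 0.02 * 4.5
                         : 0.02 * x1 / (1.0 - exp(-x1 / 4.5));
        const double B = (fabs(x2) < 1e-7) ? 0.05 * 4.5
                         : 0.05 * x2 / (exp(x2 / 4.5) - 1.0);
        tau_mCaS = p_tCaS_scale * 0.001 / (A + B);
    } else {
        /* sigmoid-sum form: slow activation subthreshold, fast above */
        tau_mCaS = p_tCaS_scale *
            (0.001 + 0.02 / (1.0 + exp(x1 / 4.5)) +
                     0.05 / (1.0 + exp(x2 / 4.5)));
    }

    dy[1] = (finf(p_hNaF_slope, p_hNaF_vhalf, V) - hNaF) / tau_hNaF;
    dy[2] = (finf(-4.1, -43.0, V) - mNaP) / 0.001;
    dy[3] = (finf(5.0, -57.0, V) - hNaP) / 0.1;
    dy[4] = (finf(-15.0, -18.0, V) - mKDR) / tau_mKDR;
    dy[5] = (finf(5.0, -59.8, V) - hKA) / 0.02;
    dy[6] = (finf(-4.27, -45.6, V) - mCaS) / tau_mCaS;
    dy[7] = (finf(0.86, -56.34, V) - hCaS) / 0.34;

    if (p_mh_frozen > 0.5) {
        dy[8] = 0.0;
    } else {
        const double xh = V - p_mh_vhalf;
        const double mh_inf = 1.0 /
            (1.0 + 2.0 * exp(p_mh_k1 * xh) + exp(p_mh_k2 * xh));
        const double tau_h = p_tauh_scale *
            (p_tauh_base + p_tauh_amp /
             (1.0 + exp(p_tauh_slope * (V - p_tauh_vhalf))));
        dy[8] = (mh_inf - mh) / tau_h;
    }

    dy[9] = (finf(-0.4, -25.0, V) - mSyn) / 0.05;

    dy[10] = p_M * (p_Nae - Nai) -
        p_alpha * (IhNa + ILNa + INaF + INaP + 3.0 * IPump);
}

void hco_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (p_ncell > 1.5) {
        cell_derivs(y, y[11 + 9], ydot);            /* cell1 <- mSyn of cell2 */
        cell_derivs(y + 11, y[9], ydot + 11);       /* cell2 <- mSyn of cell1 */
    } else {
        cell_derivs(y, 0.0, ydot);                  /* decoupled single cell */
    }
}
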