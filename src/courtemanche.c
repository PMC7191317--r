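/* Courtemanche-Ramirez-Nattel human atrial myocyte model (1998),
 * transcribed from the published equation set / CellML encoding.
 * Modifications used here: [Na+]i and [K+]i are held constant (their
 * derivatives are zeroed), and the stimulus is an absolute inward
 * current in pA applied as a square pulse.
 *
 * Units: time ms, voltage mV, concentrations mM, currents pA
 * (densities in pA/pF multiplied by Cm).
 *
 * deSolve compiled-model interface: crn_init / crn_derivs.
 *
 * Parameter vector (length 22):
 *  0 g_Na (nS/pF)    1 g_K1     2 g_to     3 fG_Kur (mult)  4 g_Kr
 *  5 g_Ks            6 g_CaL    7 g_bNa    8 g_bCa          9 iNaKmax (pA/pF)
 * 10 iNaCamax       11 iCaPmax 12 K_rel (/ms) 13 tau_tr (ms) 14 iupmax (mM/ms)
 * 15 K_up (mM)      16 Cm (pF) 17 Nao (mM) 18 Ko (mM)       19 Cao (mM)
 * 20 stim amplitude (pA, >0 means inward)  21 stim on (0/1)
 *
 * States (21): 0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
 * 10 d, 11 f, 12 fCa, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai,
 * 19 Caup, 20 Carel
 */

#include <R.h>
#include <math.h>

#define NPAR 22
static double p[NPAR];

void crn_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void crn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double R = 8.3143, T = 310.0, F = 96.4867;
    const double V_i = 13668.0, V_up = 1109.52, V_rel = 96.48;
    const double K_Q10 = 3.0;
    const double Km_Na_i = 10.0, Km_K_o = 1.5;
    const double K_mNa = 87.5, K_mCa = 1.38, K_sat = 0.1, gama = 0.35;
    const double CMDN_max = 0.05, TRPN_max = 0.07, CSQN_max = 10.0;
    const double Km_CMDN = 0.00238, Km_TRPN = 0.0005, Km_CSQN = 0.8;
    const double Ca_up_max = 15.0;

    double g_Na = p[0], g_K1 = p[1], g_to = p[2], fGKur = p[3], g_Kr = p[4];
    double g_Ks = p[5], g_CaL = p[6], g_bNa = p[7], g_bCa = p[8];
    double iNaKmax = p[9], iNaCamax = p[10], iCaPmax = p[11];
    double K_rel = p[12], tau_tr = p[13], iupmax = p[14], K_up = p[15];
    double Cm = p[16], Nao = p[17], Ko = p[18], Cao = p[19];
    double stim = (p[21] > 0.5) ? -p[20] : 0.0; /* inward = negative */

    double V = y[0], m = y[1], h = y[2], j = y[3], oa = y[4], oi = y[5];
    double ua = y[6], ui = y[7], xr = y[8], xs = y[9], d = y[10], f = y[11];
    double fCa = y[12], u = y[13], v = y[14], w = y[15];
    double Nai = y[16], Ki = y[17], Cai = y[18], Caup = y[19], Carel = y[20];

    double RTF = R * T / F;
    double E_Na = RTF * log(Nao / Nai);
    double E_K  = RTF * log(Ko / Ki);
    double E_Ca = 0.5 * RTF * log(Cao / Cai);

    /* fast Na+ current */
    double i_Na = Cm * g_Na * m * m * m * h * j * (V - E_Na);

    double a_m = (fabs(V + 47.13) < 1e-10) ? 3.2
        : 0.32 * (V + 47.13) / (1.0 - exp(-0.1 * (V + 47.13)));
    double b_m = 0.08 * exp(-V / 11.0);
    double a_h, b_h, a_j, b_j;
    if (V < -40.0) {
        a_h = 0.135 * exp((V + 80.0) / -6.8);
        b_h = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
        a_j = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V))
              * (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        b_j = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    } else {
        a_h = 0.0;
        b_h = 1.0 / (0.13 * (1.0 + exp((V + 10.66) / -11.1)));
        a_j = 0.0;
        b_j = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    }

    /* time-independent K+ current */
    double i_K1 = Cm * g_K1 * (V - E_K) / (1.0 + exp(0.07 * (V + 80.0)));

    /* transient outward */
    double i_to = Cm * g_to * oa * oa * oa * oi * (V - E_K);
    double a_oa = 0.65 / (exp((V + 10.0) / -8.5) + exp((V - 30.0) / -59.0));
    double b_oa = 0.65 / (2.5 + exp((V + 82.0) / 17.0));
    double tau_oa = 1.0 / ((a_oa + b_oa) * K_Q10);
    double oa_inf = 1.0 / (1.0 + exp((V + 20.47) / -17.54));
    double a_oi = 1.0 / (18.53 + exp((V + 113.7) / 10.95));
    double b_oi = 1.0 / (35.56 + exp((V + 1.26) / -7.44));
    double tau_oi = 1.0 / ((a_oi + b_oi) * K_Q10);
    double oi_inf = 1.0 / (1.0 + exp((V + 43.1) / 5.3));

    /* ultra-rapid delayed rectifier (Kv1.5); fGKur scales conductance */
    double g_Kur = fGKur * (0.005 + 0.05 / (1.0 + exp((V - 15.0) / -13.0)));
    double i_Kur = Cm * g_Kur * ua * ua * ua * ui * (V - E_K);
    double a_ua = 0.65 / (exp((V + 10.0) / -8.5) + exp((V - 30.0) / -59.0));
    double b_ua = 0.65 / (2.5 + exp((V + 82.0) / 17.0));
    double tau_ua = 1.0 / ((a_ua + b_ua) * K_Q10);
    double ua_inf = 1.0 / (1.0 + exp((V + 30.3) / -9.6));
    double a_ui = 1.0 / (21.0 + exp((V - 185.0) / -28.0));
    double b_ui = exp((V - 158.0) / 16.0);
    double tau_ui = 1.0 / ((a_ui + b_ui) * K_Q10);
    double ui_inf = 1.0 / (1.0 + exp((V - 99.45) / 27.48));

    /* rapid delayed rectifier */
    double i_Kr = Cm * g_Kr * xr * (V - E_K) / (1.0 + exp((V + 15.0) / 22.4));
    double a_xr = (fabs(V + 14.1) < 1e-10) ? 0.0015
        : 0.0003 * (V + 14.1) / (1.0 - exp((V + 14.1) / -5.0));
    double b_xr = (fabs(V - 3.3328) < 1e-10) ? 3.7836118e-4
        : 7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1.0);
    double tau_xr = 1.0 / (a_xr + b_xr);
    double xr_inf = 1.0 / (1.0 + exp((V + 14.1) / -6.5));

    /* slow delayed rectifier */
    double i_Ks = Cm * g_Ks * xs * xs * (V - E_K);
    double a_xs = (fabs(V - 19.9) < 1e-10) ? 0.00068
        : 4e-5 * (V - 19.9) / (1.0 - exp((V - 19.9) / -17.0));
    double b_xs = (fabs(V - 19.9) < 1e-10) ? 0.000315
        : 3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9.0) - 1.0);
    double tau_xs = 0.5 / (a_xs + b_xs);
    double xs_inf = 1.0 / sqrt(1.0 + exp((V - 19.9) / -12.7));

    /* L-type Ca2+ current */
    double i_CaL = Cm * g_CaL * d * f * fCa * (V - 65.0);
    double d_inf = 1.0 / (1.0 + exp((V + 10.0) / -8.0));
    double tau_d;
    if (fabs(V + 10.0) < 1e-10) {
        tau_d = 4.579 / (1.0 + exp((V + 10.0) / -6.24));
    } else {
        tau_d = (1.0 - exp((V + 10.0) / -6.24))
              / (0.035 * (V + 10.0) * (1.0 + exp((V + 10.0) / -6.24)));
    }
    double f_inf = exp(-(V + 28.0) / 6.9) / (1.0 + exp(-(V + 28.0) / 6.9));
    double tau_f = 9.0 / (0.0197 * exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
    double fCa_inf = 1.0 / (1.0 + Cai / 0.00035);
    double tau_fCa = 2.0;

    /* Na+/K+ pump */
    double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
    double f_NaK = 1.0 / (1.0 + 0.1245 * exp(-0.1 * F * V / (R * T))
                          + 0.0365 * sigma * exp(-F * V / (R * T)));
    double i_NaK = Cm * iNaKmax * f_NaK * (1.0 / (1.0 + pow(Km_Na_i / Nai, 1.5)))
                 * (Ko / (Ko + Km_K_o));

    /* Na+/Ca2+ exchanger */
    double i_NaCa = Cm * iNaCamax
        * (exp(gama * F * V / (R * T)) * Nai * Nai * Nai * Cao
           - exp((gama - 1.0) * F * V / (R * T)) * Nao * Nao * Nao * Cai)
        / ((K_mNa * K_mNa * K_mNa + Nao * Nao * Nao) * (K_mCa + Cao)
           * (1.0 + K_sat * exp((gama - 1.0) * F * V / (R * T))));

    /* background and pump currents */
    double i_bNa = Cm * g_bNa * (V - E_Na);
    double i_bCa = Cm * g_bCa * (V - E_Ca);
    double i_CaP = Cm * iCaPmax * Cai / (0.0005 + Cai);

    /* SR release, uptake, transfer */
    double i_rel = K_rel * u * u * v * w * (Carel - Cai);
    double Fn = 1000.0 * (1e-15 * V_rel * i_rel
                          - 1e-15 / (2.0 * F) * (0.5 * i_CaL - 0.2 * i_NaCa));
    double u_inf = 1.0 / (1.0 + exp(-(Fn - 3.4175e-13) / 13.67e-16));
    double tau_u = 8.0;
    double v_inf = 1.0 - 1.0 / (1.0 + exp(-(Fn - 6.835e-14) / 13.67e-16));
    double tau_v = 1.91 + 2.09 / (1.0 + exp(-(Fn - 3.4175e-13) / 13.67e-16));
    double w_inf = 1.0 - 1.0 / (1.0 + exp(-(V - 40.0) / 17.0));
    double tau_w = (fabs(V - 7.9) < 1e-10) ? (6.0 * 0.2 / 1.3)
        : 6.0 * (1.0 - exp(-(V - 7.9) / 5.0))
          / ((1.0 + 0.3 * exp(-(V - 7.9) / 5.0)) * (V - 7.9));

    double i_up = iupmax / (1.0 + K_up / Cai);
    double i_up_leak = iupmax * Caup / Ca_up_max;
    double i_tr = (Caup - Carel) / tau_tr;

    /* membrane potential */
    double i_ion = i_Na + i_K1 + i_to + i_Kur + i_Kr + i_Ks + i_bNa + i_bCa
                 + i_NaK + i_CaP + i_NaCa + i_CaL;
    ydot[0] = -(i_ion + stim) / Cm;

    ydot[1] = a_m * (1.0 - m) - b_m * m;
    ydot[2] = a_h * (1.0 - h) - b_h * h;
    ydot[3] = a_j * (1.0 - j) - b_j * j;
    ydot[4] = (oa_inf - oa) / tau_oa;
    ydot[5] = (oi_inf - oi) / tau_oi;
    ydot[6] = (ua_inf - ua) / tau_ua;
    ydot[7] = (ui_inf - ui) / tau_ui;
    ydot[8] = (xr_inf - xr) / tau_xr;
    ydot[9] = (xs_inf - xs) / tau_xs;
    ydot[10] = (d_inf - d) / tau_d;
    ydot[11] = (f_inf - f) / tau_f;
    ydot[12] = (fCa_inf - fCa) / tau_fCa;
    ydot[13] = (u_inf - u) / tau_u;
    ydot[14] = (v_inf - v) / tau_v;
    ydot[15] = (w_inf - w) / tau_w;

    /* intracellular Na+ and K+ held constant (stability modification) */
    ydot[16] = 0.0;
    ydot[17] = 0.0;

    double B1 = (2.0 * i_NaCa - (i_CaP + i_CaL + i_bCa)) / (2.0 * V_i * F)
              + (V_up * (i_up_leak - i_up) + i_rel * V_rel) / V_i;
    double B2 = 1.0 + TRPN_max * Km_TRPN / ((Cai + Km_TRPN) * (Cai + Km_TRPN))
              + CMDN_max * Km_CMDN / ((Cai + Km_CMDN) * (Cai + Km_CMDN));
    ydot[18] = B1 / B2;
    ydot[19] = i_up - i_up_leak - i_tr * V_rel / V_up;
    ydot[20] = (i_tr - i_rel)
        / (1.0 + CSQN_max * Km_CSQN / ((Carel + Km_CSQN) * (Carel + Km_CSQN)));

    /* auxiliary outputs: current densities in pA/pF */
    if (*ip >= 3) {
        yout[0] = i_Kur / Cm;
        yout[1] = i_CaL / Cm;
        yout[2] = i_Kr / Cm;
    }
}
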