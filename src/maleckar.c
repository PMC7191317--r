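/* Maleckar et al. human atrial myocyte model (2009): the Nygren et al.
 * (1998) cell with reformulated transient-outward and ultra-rapid
 * K+ currents and zero electroneutral Na+ influx. The acetylcholine
 * activated K+ current is fixed to zero here.
 *
 * Units follow the original encoding: time s, voltage mV,
 * concentrations mM, currents pA, capacitance nF.
 *
 * Parameter vector (length 24):
 *  0 P_Na (nL/s)   1 g_K1 (nS)  2 g_t    3 g_Kur   4 g_Kr   5 g_Ks
 *  6 g_CaL         7 g_bNa      8 g_bCa  9 iNaKmax (pA)
 * 10 K_NaCa (pA/mM^4) 11 iCaPmax (pA) 12 alpha_rel (pA/mM) 13 tau_tr (s)
 * 14 iupmax (pA)  15 k_cyca (mM) 16 k_srca (mM) 17 k_xcs (-)
 * 18 Cm (nF)      19 Nab (mM)  20 Kb (mM) 21 Cab (mM)
 * 22 stim amplitude (pA, >0 inward) 23 stim on (0/1)
 *
 * States (29): 0 V, 1 m, 2 h1, 3 h2, 4 dL, 5 fL1, 6 fL2, 7 r, 8 s,
 * 9 a_ur, 10 i_ur, 11 n, 12 pa, 13 Nac, 14 Kc, 15 Cac, 16 Nai, 17 Ki,
 * 18 Cai, 19 Cad, 20 O_C, 21 O_TC, 22 O_TMgC, 23 O_TMgMg, 24 O_Calse,
 * 25 Carel, 26 Caup, 27 F1, 28 F2
 */

#include <R.h>
#include <math.h>

#define NPAR 24
static double p[NPAR];

void mal_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void mal_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double R = 8314.0, T = 306.15, F = 96487.0;
    const double Vol_i = 0.005884, Vol_d = 0.02 * 0.005884;
    const double Vol_c = 0.000800224, Vol_up = 0.0003969, Vol_rel = 0.0000441;
    const double tau_Na = 14.3, tau_K = 10.0, tau_Ca = 24.7, tau_di = 0.01;
    const double Mg_i = 2.5;
    const double k_NaK_K = 1.0, k_NaK_Na = 11.0;
    const double d_NaCa = 0.0003, gama = 0.45;
    const double k_CaP = 0.0002;
    const double E_Ca_app = 60.0, k_Ca = 0.025;
    const double k_rel_i = 0.0003, k_rel_d = 0.003, r_recov = 0.815;

    double P_Na = p[0], g_K1 = p[1], g_t = p[2], g_Kur = p[3], g_Kr = p[4];
    double g_Ks = p[5], g_CaL = p[6], g_bNa = p[7], g_bCa = p[8];
    double iNaKmax = p[9], K_NaCa = p[10], iCaPmax = p[11];
    double alpha_rel = p[12], tau_tr = p[13], iupmax = p[14];
    double k_cyca = p[15], k_srca = p[16], k_xcs = p[17];
    double Cm = p[18], Nab = p[19], Kb = p[20], Cab = p[21];
    double stim = (p[23] > 0.5) ? -p[22] : 0.0;

    double V = y[0], m = y[1], h1 = y[2], h2 = y[3], dL = y[4];
    double fL1 = y[5], fL2 = y[6], r = y[7], s = y[8];
    double a_ur = y[9], i_ur = y[10], n = y[11], pa = y[12];
    double Nac = y[13], Kc = y[14], Cac = y[15];
    double Nai = y[16], Ki = y[17], Cai = y[18], Cad = y[19];
    double O_C = y[20], O_TC = y[21], O_TMgC = y[22], O_TMgMg = y[23];
    double O_Calse = y[24], Carel = y[25], Caup = y[26];
    double F1 = y[27], F2 = y[28];

    double RTF = R * T / F;
    double E_Na = RTF * log(Nac / Nai);
    double E_K  = RTF * log(Kc / Ki);
    double E_Ca = 0.5 * RTF * log(Cac / Cai);
    double VFRT = V * F / (R * T);

    /* fast Na+ current (GHK-type); V -> 0 limit of the driving term is F */
    double i_Na;
    double gma = m * m * m * h1 * h2;
    if (fabs(V) < 1e-7) {
        i_Na = P_Na * gma * Nac * F * (exp((V - E_Na) * F / (R * T)) - 1.0);
    } else {
        i_Na = P_Na * gma * Nac * F * VFRT
             * (exp((V - E_Na) * F / (R * T)) - 1.0) / (exp(VFRT) - 1.0);
    }
    double m_inf = 1.0 / (1.0 + exp((V + 27.12) / -8.21));
    double m_fac = (V + 25.57) / 28.8;
    double tau_m = 4.2e-5 * exp(-m_fac * m_fac) + 2.4e-5;
    double h_inf = 1.0 / (1.0 + exp((V + 63.6) / 5.3));
    double h_fac = 1.0 / (1.0 + exp((V + 35.1) / 3.2));
    double tau_h1 = 0.03 * h_fac + 0.0003;
    double tau_h2 = 0.12 * h_fac + 0.003;

    /* L-type Ca2+ current */
    double f_Ca = Cad / (Cad + k_Ca);
    double i_CaL = g_CaL * dL * (f_Ca * fL1 + (1.0 - f_Ca) * fL2)
                 * (V - E_Ca_app);
    double dL_inf = 1.0 / (1.0 + exp((V + 9.0) / -5.8));
    double dL_fac = (V + 35.0) / 30.0;
    double tau_dL = 0.0027 * exp(-dL_fac * dL_fac) + 0.002;
    double fL_inf = 1.0 / (1.0 + exp((V + 27.4) / 7.1));
    double fL_fac = V + 40.0;
    double tau_fL1 = 0.161 * exp(-(fL_fac / 14.4) * (fL_fac / 14.4)) + 0.01;
    double tau_fL2 = 1.3323 * exp(-(fL_fac / 14.2) * (fL_fac / 14.2)) + 0.0626;

    /* transient outward K+ current (reformulated) */
    double i_t = g_t * r * s * (V - E_K);
    double r_inf = 1.0 / (1.0 + exp((V - 1.0) / -11.0));
    double tau_r = 0.0035 * exp(-(V / 30.0) * (V / 30.0)) + 0.0015;
    double s_inf = 1.0 / (1.0 + exp((V + 40.5) / 11.5));
    double s_fac = (V + 52.45) / 15.8827;
    double tau_s = 0.025635 * exp(-s_fac * s_fac) + 0.01414;

    /* ultra-rapid K+ current (Kv1.5, reformulated) */
    double i_Kur = g_Kur * a_ur * i_ur * (V - E_K);
    double aur_inf = 1.0 / (1.0 + exp(-(V + 6.0) / 8.6));
    double iur_inf = 1.0 / (1.0 + exp((V + 7.5) / 10.0));
    double tau_aur = 0.009 / (1.0 + exp((V + 5.0) / 12.0)) + 0.0005;
    double tau_iur = 0.59 / (1.0 + exp((V + 60.0) / 10.0)) + 3.05;

    /* delayed rectifiers */
    double i_Ks = g_Ks * n * (V - E_K);
    double n_inf = 1.0 / (1.0 + exp((V - 19.9) / -12.7));
    double n_fac = (V - 20.0) / 20.0;
    double tau_n = 0.7 + 0.4 * exp(-n_fac * n_fac);

    double p_i = 1.0 / (1.0 + exp((V + 55.0) / 24.0));
    double i_Kr = g_Kr * pa * p_i * (V - E_K);
    double pa_inf = 1.0 / (1.0 + exp((V + 15.0) / -6.0));
    double pa_fac = (V + 20.1376) / 22.1996;
    double tau_pa = 0.03118 + 0.21718 * exp(-pa_fac * pa_fac);

    /* inward rectifier */
    double i_K1 = g_K1 * pow(Kc / 1.0, 0.4457) * (V - E_K)
        / (1.0 + exp(1.5 * (V - E_K + 3.6) * F / (R * T)));

    /* background currents */
    double i_bNa = g_bNa * (V - E_Na);
    double i_bCa = g_bCa * (V - E_Ca);

    /* Na+/K+ pump, Ca2+ pump, Na+/Ca2+ exchange */
    double Nai15 = pow(Nai, 1.5);
    double i_NaK = iNaKmax * (Kc / (Kc + k_NaK_K))
                 * (Nai15 / (Nai15 + pow(k_NaK_Na, 1.5)))
                 * (V + 150.0) / (V + 200.0);
    double i_CaP = iCaPmax * Cai / (Cai + k_CaP);
    double i_NaCa = K_NaCa
        * (Nai * Nai * Nai * Cac * exp(gama * VFRT)
           - Nac * Nac * Nac * Cai * exp((gama - 1.0) * VFRT))
        / (1.0 + d_NaCa * (Nac * Nac * Nac * Cai + Nai * Nai * Nai * Cac));

    /* electroneutral Na+ influx removed in this formulation */
    double phi_Na_en = 0.0;

    /* SR uptake, transfer, release */
    double i_up = iupmax * (Cai / k_cyca - k_xcs * k_xcs * Caup / k_srca)
        / ((Cai + k_cyca) / k_cyca + k_xcs * (Caup + k_srca) / k_srca);
    double i_tr = (Caup - Carel) * 2.0 * F * Vol_rel / tau_tr;
    double relf = F2 / (F2 + 0.25);
    double i_rel = alpha_rel * relf * relf * (Carel - Cai);
    double acti = Cai / (Cai + k_rel_i);
    double actd = Cad / (Cad + k_rel_d);
    double r_act = 203.8 * (acti * acti * acti * acti
                            + actd * actd * actd * actd);
    double r_inact = 33.96 + 339.6 * acti * acti * acti * acti;

    /* diffusion restricted subspace */
    double i_di = (Cad - Cai) * 2.0 * F * Vol_d / tau_di;

    /* intracellular Ca2+ buffers */
    double dO_C = 200000.0 * Cai * (1.0 - O_C) - 476.0 * O_C;
    double dO_TC = 78400.0 * Cai * (1.0 - O_TC) - 392.0 * O_TC;
    double dO_TMgC = 200000.0 * Cai * (1.0 - O_TMgC - O_TMgMg) - 6.6 * O_TMgC;
    double dO_TMgMg = 2000.0 * Mg_i * (1.0 - O_TMgC - O_TMgMg) - 666.0 * O_TMgMg;
    double dO_Calse = 480.0 * Carel * (1.0 - O_Calse) - 400.0 * O_Calse;

    double i_ion = i_Na + i_CaL + i_t + i_Kur + i_K1 + i_Kr + i_Ks
                 + i_bNa + i_bCa + i_NaK + i_CaP + i_NaCa;

    ydot[0] = -(i_ion + stim) / Cm; /* pA / nF = mV/s */
    ydot[1] = (m_inf - m) / tau_m;
    ydot[2] = (h_inf - h1) / tau_h1;
    ydot[3] = (h_inf - h2) / tau_h2;
    ydot[4] = (dL_inf - dL) / tau_dL;
    ydot[5] = (fL_inf - fL1) / tau_fL1;
    ydot[6] = (fL_inf - fL2) / tau_fL2;
    ydot[7] = (r_inf - r) / tau_r;
    ydot[8] = (s_inf - s) / tau_s;
    ydot[9] = (aur_inf - a_ur) / tau_aur;
    ydot[10] = (iur_inf - i_ur) / tau_iur;
    ydot[11] = (n_inf - n) / tau_n;
    ydot[12] = (pa_inf - pa) / tau_pa;

    /* cleft space concentrations */
    ydot[13] = (Nab - Nac) / tau_Na
             + (i_Na + i_bNa + 3.0 * i_NaK + 3.0 * i_NaCa + phi_Na_en)
               / (Vol_c * F);
    ydot[14] = (Kb - Kc) / tau_K
             + (i_t + i_Kur + i_K1 + i_Ks + i_Kr - 2.0 * i_NaK)
               / (Vol_c * F);
    ydot[15] = (Cab - Cac) / tau_Ca
             + (i_CaL + i_bCa + i_CaP - 2.0 * i_NaCa) / (2.0 * Vol_c * F);

    /* intracellular concentrations */
    ydot[16] = -(i_Na + i_bNa + 3.0 * i_NaK + 3.0 * i_NaCa + phi_Na_en)
               / (Vol_i * F);
    ydot[17] = -(i_t + i_Kur + i_K1 + i_Ks + i_Kr - 2.0 * i_NaK + stim)
               / (Vol_i * F);
    ydot[18] = -(-i_di + i_bCa + i_CaP - 2.0 * i_NaCa + i_up - i_rel)
               / (2.0 * Vol_i * F)
             - (0.045 * dO_C + 0.08 * dO_TC + 0.16 * dO_TMgC);
    ydot[19] = -(i_CaL + i_di) / (2.0 * Vol_d * F);

    ydot[20] = dO_C;
    ydot[21] = dO_TC;
    ydot[22] = dO_TMgC;
    ydot[23] = dO_TMgMg;
    ydot[24] = dO_Calse;

    ydot[25] = (i_tr - i_rel) / (2.0 * Vol_rel * F) - 31.0 * dO_Calse;
    ydot[26] = (i_up - i_tr) / (2.0 * Vol_up * F);
    ydot[27] = r_recov * (1.0 - F1 - F2) - r_act * F1;
    ydot[28] = r_act * F1 - r_inact * F2;

    /* auxiliary outputs: current densities in pA/pF (Cm nF -> 1000*Cm pF) */
    if (*ip >= 3) {
        double CmpF = Cm * 1000.0;
        yout[0] = i_Kur / CmpF;
        yout[1] = i_CaL / CmpF;
        yout[2] = i_Kr / CmpF;
    }
}
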