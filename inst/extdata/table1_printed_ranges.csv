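model,input,central,printed_range,percent,units,note
courtemanche,G_Na,7.8,5.85-11.70,50,nS/pF,printed lower endpoint inconsistent with the percentage rule (0.5*7.8=3.9)
courtemanche,G_K1,0.09,0.045-0.018,25,nS/pF,printed endpoints inconsistent (0.75*0.09=0.0675; 1.25*0.09=0.1125)
courtemanche,G_to,0.165,0.0826-0.0330,50,nS/pF,printed upper endpoint inconsistent (1.5*0.165=0.2475)
courtemanche,fG_Kur,1.0,0.50-1.50,50,1,
courtemanche,G_Kr,0.0294,0.0147-0.0441,50,nS/pF,
courtemanche,G_Ks,0.1294,0.0647-0.1941,50,nS/pF,
courtemanche,G_CaL,0.1237,0.0619-0.1856,50,nS/pF,
courtemanche,G_bNa,0.0006,0.0003-0.0010,50,nS/pF,
courtemanche,G_bCa,0.0011,0.0005-0.0017,50,nS/pF,
courtemanche,i_NaK_max,0.5993,0.2997-0.8990,50,pA/pF,
courtemanche,i_NaCa_max,1600.0,800.00-2400.0,50,pA/pF,
courtemanche,i_pCa_max,0.275,0.1375-0.4125,50,pA/pF,
courtemanche,K_rel,0.30,0.15-0.45,50,1/ms,printed central 0.30 conflicts with the published model default 30 /ms; the default is used here
courtemanche,tau_tr,180.0,90.0-270.0,50,ms,
courtemanche,i_up_max,0.005,0.0025-0.0075,50,mM/ms,
courtemanche,K_up,0.00092,0.00046-0.0014,50,mM,
courtemanche,C_m,100.0,75.0-125.0,25,pF,
courtemanche,Na_o,140.0,126.0-154.0,10,mM,
courtemanche,K_o,5.4,4.86-5.94,10,mM,
courtemanche,Ca_o,1.8,1.62-1.98,10,mM,
maleckar,P_Na,0.0018,0.0009-0.0027,50,nL/s,
maleckar,G_K1,3.1,2.325-3.875,25,nS,
maleckar,G_t,8.25,4.125-12.375,50,nS,
maleckar,G_Kur,2.25,1.125-3.375,50,nS,
maleckar,G_Kr,0.5,0.250-0.750,50,nS,
maleckar,G_Ks,1.0,0.50-1.50,50,nS,
maleckar,G_CaL,6.75,3.375-10.125,50,nS,
maleckar,G_bNa,0.0605,0.303-0.909,50,nS,printed endpoints inconsistent with the central value (likely a decimal slip)
maleckar,G_bCa,0.0590,0.0295-0.0885,50,nS,
maleckar,i_NaK_max,68.55,34.27-102.82,50,pA,
maleckar,K_NaCa,0.0750,0.0375-0.1125,50,pA/mM^4,
maleckar,i_pCa_max,4.0,2.0-6.0,50,pA,
maleckar,alpha_rel,200000,100000-300000,50,pA/mM,
maleckar,tau_tr,0.01,0.005-0.015,50,s,
maleckar,i_up_max,2800,1400-4300,50,pA,printed upper endpoint inconsistent (1.5*2800=4200)
maleckar,K_cyca,0.0003,0.00015-0.00045,50,mM,
maleckar,K_srca,0.5,0.25-0.75,50,mM,
maleckar,K_xcs,0.4,0.2-0.6,50,1,
maleckar,C_m,50,37.5-62.5,25,pF,
maleckar,Na_o,140.0,126.0-154.0,10,mM,
maleckar,K_o,5.4,4.86-5.94,10,mM,
maleckar,Ca_o,1.8,1.62-1.98,10,mM,
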