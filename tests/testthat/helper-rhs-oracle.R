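# Independent R transcriptions of the two cell-model right-hand sides,
# used as an oracle for the compiled derivatives. Written from the
# published equation sets separately from the C code.

crn_rhs_R <- function(y, p) {
  R <- 8.3143; T <- 310; F <- 96.4867
  V_i <- 13668; V_up <- 1109.52; V_rel <- 96.48
  KQ10 <- 3
  V <- y["V"]; m <- y["m"]; h <- y["h"]; j <- y["j"]
  oa <- y["oa"]; oi <- y["oi"]; ua <- y["ua"]; ui <- y["ui"]
  xr <- y["xr"]; xs <- y["xs"]; d <- y["d"]; f <- y["f"]; fCa <- y["fCa"]
  u <- y["u"]; v <- y["v"]; w <- y["w"]
  Nai <- y["Nai"]; Ki <- y["Ki"]; Cai <- y["Cai"]
  Caup <- y["Caup"]; Carel <- y["Carel"]
  Cm <- p$C_m; Nao <- p$Na_o; Ko <- p$K_o; Cao <- p$Ca_o

  ENa <- R * T / F * log(Nao / Nai)
  EK <- R * T / F * log(Ko / Ki)
  ECa <- R * T / (2 * F) * log(Cao / Cai)

  iNa <- Cm * p$G_Na * m^3 * h * j * (V - ENa)
  am <- if (abs(V + 47.13) < 1e-10) 3.2 else
    0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  bm <- 0.08 * exp(-V / 11)
  if (V < -40) {
    ah <- 0.135 * exp(-(V + 80) / 6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  iK1 <- Cm * p$G_K1 * (V - EK) / (1 + exp(0.07 * (V + 80)))
  ito <- Cm * p$G_to * oa^3 * oi * (V - EK)
  aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  boa <- 0.65 / (2.5 + exp((V + 82) / 17))
  oainf <- 1 / (1 + exp(-(V + 20.47) / 17.54))
  tauoa <- 1 / ((aoa + boa) * KQ10)
  aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
  boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
  oiinf <- 1 / (1 + exp((V + 43.1) / 5.3))
  tauoi <- 1 / ((aoi + boi) * KQ10)
  gKur <- p$fG_Kur * (0.005 + 0.05 / (1 + exp(-(V - 15) / 13)))
  iKur <- Cm * gKur * ua^3 * ui * (V - EK)
  aua <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  bua <- 0.65 / (2.5 + exp((V + 82) / 17))
  uainf <- 1 / (1 + exp(-(V + 30.3) / 9.6))
  tauua <- 1 / ((aua + bua) * KQ10)
  aui <- 1 / (21 + exp(-(V - 185) / 28))
  bui <- exp((V - 158) / 16)
  uiinf <- 1 / (1 + exp((V - 99.45) / 27.48))
  tauui <- 1 / ((aui + bui) * KQ10)
  iKr <- Cm * p$G_Kr * xr * (V - EK) / (1 + exp((V + 15) / 22.4))
  axr <- if (abs(V + 14.1) < 1e-10) 0.0015 else
    3e-4 * (V + 14.1) / (1 - exp(-(V + 14.1) / 5))
  bxr <- if (abs(V - 3.3328) < 1e-10) 3.7836118e-4 else
    7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
  xrinf <- 1 / (1 + exp(-(V + 14.1) / 6.5))
  tauxr <- 1 / (axr + bxr)
  iKs <- Cm * p$G_Ks * xs^2 * (V - EK)
  axs <- if (abs(V - 19.9) < 1e-10) 6.8e-4 else
    4e-5 * (V - 19.9) / (1 - exp(-(V - 19.9) / 17))
  bxs <- if (abs(V - 19.9) < 1e-10) 3.15e-4 else
    3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)
  xsinf <- (1 + exp(-(V - 19.9) / 12.7))^-0.5
  tauxs <- 0.5 / (axs + bxs)
  iCaL <- Cm * p$G_CaL * d * f * fCa * (V - 65)
  dinf <- 1 / (1 + exp(-(V + 10) / 8))
  taud <- if (abs(V + 10) < 1e-10) 4.579 / (1 + exp(-(V + 10) / 6.24)) else
    (1 - exp(-(V + 10) / 6.24)) /
      (0.035 * (V + 10) * (1 + exp(-(V + 10) / 6.24)))
  finf <- 1 / (1 + exp((V + 28) / 6.9))
  tauf <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
  fCainf <- 1 / (1 + Cai / 0.00035)
  sigma <- (exp(Nao / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * F * V / (R * T)) +
                 0.0365 * sigma * exp(-F * V / (R * T)))
  iNaK <- Cm * p$i_NaK_max * fNaK / (1 + (10 / Nai)^1.5) *
    Ko / (Ko + 1.5)
  g <- 0.35
  iNaCa <- Cm * p$i_NaCa_max *
    (exp(g * F * V / (R * T)) * Nai^3 * Cao -
       exp((g - 1) * F * V / (R * T)) * Nao^3 * Cai) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) *
       (1 + 0.1 * exp((g - 1) * F * V / (R * T))))
  ibNa <- Cm * p$G_bNa * (V - ENa)
  ibCa <- Cm * p$G_bCa * (V - ECa)
  iCaP <- Cm * p$i_pCa_max * Cai / (0.0005 + Cai)
  irel <- p$K_rel * u^2 * v * w * (Carel - Cai)
  Fn <- 1e3 * (1e-15 * V_rel * irel -
                 1e-15 / (2 * F) * (0.5 * iCaL - 0.2 * iNaCa))
  uinf <- 1 / (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))
  vinf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 13.67e-16))
  tauv <- 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))
  winf <- 1 - 1 / (1 + exp(-(V - 40) / 17))
  tauw <- if (abs(V - 7.9) < 1e-10) 6 * 0.2 / 1.3 else
    6 * (1 - exp(-(V - 7.9) / 5)) /
      ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9))
  iup <- p$i_up_max / (1 + p$K_up / Cai)
  iupleak <- p$i_up_max * Caup / 15
  itr <- (Caup - Carel) / p$tau_tr

  iion <- iNa + iK1 + ito + iKur + iKr + iKs + ibNa + ibCa + iNaK +
    iCaP + iNaCa + iCaL
  B1 <- (2 * iNaCa - (iCaP + iCaL + ibCa)) / (2 * V_i * F) +
    (V_up * (iupleak - iup) + irel * V_rel) / V_i
  B2 <- 1 + 0.07 * 0.0005 / (Cai + 0.0005)^2 +
    0.05 * 0.00238 / (Cai + 0.00238)^2
  unname(c(
    -iion / Cm,
    am * (1 - m) - bm * m, ah * (1 - h) - bh * h, aj * (1 - j) - bj * j,
    (oainf - oa) / tauoa, (oiinf - oi) / tauoi,
    (uainf - ua) / tauua, (uiinf - ui) / tauui,
    (xrinf - xr) / tauxr, (xsinf - xs) / tauxs,
    (dinf - d) / taud, (finf - f) / tauf, (fCainf - fCa) / 2,
    (uinf - u) / 8, (vinf - v) / tauv, (winf - w) / tauw,
    0, 0,
    B1 / B2,
    iup - iupleak - itr * V_rel / V_up,
    (itr - irel) / (1 + 10 * 0.8 / (Carel + 0.8)^2)
  ))
}

mal_rhs_R <- function(y, p) {
  R <- 8314; T <- 306.15; F <- 96487
  Voli <- 0.005884; Vold <- 0.02 * Voli
  Volc <- 0.000800224; Volup <- 0.0003969; Volrel <- 0.0000441
  V <- y["V"]; m <- y["m"]; h1 <- y["h1"]; h2 <- y["h2"]
  dL <- y["dL"]; fL1 <- y["fL1"]; fL2 <- y["fL2"]
  r <- y["r"]; s <- y["s"]; aur <- y["a_ur"]; iur <- y["i_ur"]
  n <- y["n"]; pa <- y["pa"]
  Nac <- y["Nac"]; Kc <- y["Kc"]; Cac <- y["Cac"]
  Nai <- y["Nai"]; Ki <- y["Ki"]; Cai <- y["Cai"]; Cad <- y["Cad"]
  OC <- y["O_C"]; OTC <- y["O_TC"]; OTMgC <- y["O_TMgC"]
  OTMgMg <- y["O_TMgMg"]; OCalse <- y["O_Calse"]
  Carel <- y["Carel"]; Caup <- y["Caup"]; F1 <- y["F1"]; F2 <- y["F2"]
  Cm <- p$C_m / 1000

  RTF <- R * T / F
  ENa <- RTF * log(Nac / Nai)
  EK <- RTF * log(Kc / Ki)
  ECa <- RTF / 2 * log(Cac / Cai)

  iNa <- p$P_Na * m^3 * h1 * h2 * Nac * V * F^2 / (R * T) *
    (exp((V - ENa) * F / (R * T)) - 1) / (exp(V * F / (R * T)) - 1)
  minf <- 1 / (1 + exp(-(V + 27.12) / 8.21))
  taum <- 4.2e-5 * exp(-((V + 25.57) / 28.8)^2) + 2.4e-5
  hinf <- 1 / (1 + exp((V + 63.6) / 5.3))
  hfac <- 1 / (1 + exp((V + 35.1) / 3.2))
  tauh1 <- 0.03 * hfac + 3e-4
  tauh2 <- 0.12 * hfac + 0.003

  fca <- Cad / (Cad + 0.025)
  iCaL <- p$G_CaL * dL * (fca * fL1 + (1 - fca) * fL2) * (V - 60)
  dLinf <- 1 / (1 + exp(-(V + 9) / 5.8))
  taudL <- 0.0027 * exp(-((V + 35) / 30)^2) + 0.002
  fLinf <- 1 / (1 + exp((V + 27.4) / 7.1))
  taufL1 <- 0.161 * exp(-((V + 40) / 14.4)^2) + 0.01
  taufL2 <- 1.3323 * exp(-((V + 40) / 14.2)^2) + 0.0626

  it <- p$G_t * r * s * (V - EK)
  rinf <- 1 / (1 + exp(-(V - 1) / 11))
  taur <- 0.0035 * exp(-(V / 30)^2) + 0.0015
  sinf <- 1 / (1 + exp((V + 40.5) / 11.5))
  taus <- 0.025635 * exp(-((V + 52.45) / 15.8827)^2) + 0.01414

  iKur <- p$G_Kur * aur * iur * (V - EK)
  aurinf <- 1 / (1 + exp(-(V + 6) / 8.6))
  iurinf <- 1 / (1 + exp((V + 7.5) / 10))
  tauaur <- 0.009 / (1 + exp((V + 5) / 12)) + 5e-4
  tauiur <- 0.59 / (1 + exp((V + 60) / 10)) + 3.05

  iKs <- p$G_Ks * n * (V - EK)
  ninf <- 1 / (1 + exp(-(V - 19.9) / 12.7))
  taun <- 0.7 + 0.4 * exp(-((V - 20) / 20)^2)
  pi_ <- 1 / (1 + exp((V + 55) / 24))
  iKr <- p$G_Kr * pa * pi_ * (V - EK)
  painf <- 1 / (1 + exp(-(V + 15) / 6))
  taupa <- 0.03118 + 0.21718 * exp(-((V + 20.1376) / 22.1996)^2)

  iK1 <- p$G_K1 * Kc^0.4457 * (V - EK) /
    (1 + exp(1.5 * (V - EK + 3.6) * F / (R * T)))
  ibNa <- p$G_bNa * (V - ENa)
  ibCa <- p$G_bCa * (V - ECa)
  iNaK <- p$i_NaK_max * Kc / (Kc + 1) * Nai^1.5 / (Nai^1.5 + 11^1.5) *
    (V + 150) / (V + 200)
  iCaP <- p$i_pCa_max * Cai / (Cai + 2e-4)
  g <- 0.45
  iNaCa <- p$K_NaCa * (Nai^3 * Cac * exp(g * V * F / (R * T)) -
                         Nac^3 * Cai * exp((g - 1) * V * F / (R * T))) /
    (1 + 0.0003 * (Nac^3 * Cai + Nai^3 * Cac))

  iup <- p$i_up_max *
    (Cai / p$K_cyca - p$K_xcs^2 * Caup / p$K_srca) /
    ((Cai + p$K_cyca) / p$K_cyca + p$K_xcs * (Caup + p$K_srca) / p$K_srca)
  itr <- (Caup - Carel) * 2 * F * Volrel / p$tau_tr
  irel <- p$alpha_rel * (F2 / (F2 + 0.25))^2 * (Carel - Cai)
  racti <- (Cai / (Cai + 0.0003))^4
  ract <- 203.8 * (racti + (Cad / (Cad + 0.003))^4)
  rinact <- 33.96 + 339.6 * racti
  idi <- (Cad - Cai) * 2 * F * Vold / 0.01

  dOC <- 2e5 * Cai * (1 - OC) - 476 * OC
  dOTC <- 78400 * Cai * (1 - OTC) - 392 * OTC
  dOTMgC <- 2e5 * Cai * (1 - OTMgC - OTMgMg) - 6.6 * OTMgC
  dOTMgMg <- 2000 * 2.5 * (1 - OTMgC - OTMgMg) - 666 * OTMgMg
  dOCalse <- 480 * Carel * (1 - OCalse) - 400 * OCalse

  iion <- iNa + iCaL + it + iKur + iK1 + iKr + iKs + ibNa + ibCa +
    iNaK + iCaP + iNaCa
  unname(c(
    -iion / Cm,
    (minf - m) / taum, (hinf - h1) / tauh1, (hinf - h2) / tauh2,
    (dLinf - dL) / taudL, (fLinf - fL1) / taufL1, (fLinf - fL2) / taufL2,
    (rinf - r) / taur, (sinf - s) / taus,
    (aurinf - aur) / tauaur, (iurinf - iur) / tauiur,
    (ninf - n) / taun, (painf - pa) / taupa,
    (p$Na_o - Nac) / 14.3 + (iNa + ibNa + 3 * iNaK + 3 * iNaCa) / (Volc * F),
    (p$K_o - Kc) / 10 + (it + iKur + iK1 + iKs + iKr - 2 * iNaK) / (Volc * F),
    (p$Ca_o - Cac) / 24.7 + (iCaL + ibCa + iCaP - 2 * iNaCa) / (2 * Volc * F),
    -(iNa + ibNa + 3 * iNaK + 3 * iNaCa) / (Voli * F),
    -(it + iKur + iK1 + iKs + iKr - 2 * iNaK) / (Voli * F),
    -(-idi + ibCa + iCaP - 2 * iNaCa + iup - irel) / (2 * Voli * F) -
      (0.045 * dOC + 0.08 * dOTC + 0.16 * dOTMgC),
    -(iCaL + idi) / (2 * Vold * F),
    dOC, dOTC, dOTMgC, dOTMgMg, dOCalse,
    (itr - irel) / (2 * Volrel * F) - 31 * dOCalse,
    (iup - itr) / (2 * Volup * F),
    0.815 * (1 - F1 - F2) - ract * F1,
    ract * F1 - rinact * F2
  ))
}

# Exact derivative of the compiled model at state y: a single explicit
# Euler step of length dt gives y + dt * f(y).
compiled_rhs <- function(model, y, params) {
  p <- apsens:::check_params(model, params)
  if (model == "courtemanche") {
    pv <- c(unlist(p[apsens:::crn_par_order]), 2000, 0)
    fn <- list(derivs = "crn_derivs", init = "crn_init")
    dt <- 1e-5
  } else {
    pl <- p
    pl$C_m <- pl$C_m / 1000
    pv <- c(unlist(pl[apsens:::mal_par_order]), 750, 0)
    fn <- list(derivs = "mal_derivs", init = "mal_init")
    dt <- 1e-8
  }
  out <- deSolve::ode(y = y, times = c(0, dt), func = fn$derivs,
                      parms = pv, dllname = "apsens", initfunc = fn$init,
                      nout = 3, method = "euler", hini = dt)
  unname(drop((out[2, 1 + seq_along(y)] - y) / dt))
}
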