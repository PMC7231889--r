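# Independent literal transcription of the cell-model equations, used as the
# oracle for the compiled implementation. Straight-line R, written against
# the same published equation set but sharing no code with src/.

oracle_eval <- function(state, params, t = 0, stim = 0) {
  k <- as.list(params$constants)
  env <- params$environment
  tm <- as.list(params$tau_q10 * params$tau_scale)
  F <- 96485.3415; Rg <- 8.314472
  Tk <- 273.15 + env$temperature
  RTF <- Rg * Tk / F

  V <- state[["Vm"]]; Vm <- V * 1000
  Cai <- state[["Cai"]]; CaSR <- state[["Ca_SR"]]; Nai <- state[["Nai"]]

  E_Na <- RTF * log(env$Nao / Nai)
  E_Ca <- 0.5 * RTF * log(env$Cao / Cai)
  E_K <- RTF * log(env$Ko / k$Ki)
  E_Ks <- RTF * log((env$Ko + k$PkNa * env$Nao) / (k$Ki + k$PkNa * Nai))

  ## fast Na+ current
  m_inf <- 1 / (1 + exp(-(Vm + 39) / 11.2))
  tau_m <- (1e-5 + 1.3e-4 * exp(-((Vm + 48) / 15)^2) +
              4.5e-5 / (1 + exp(-(Vm + 42) / 5))) * tm$Na_act
  h_inf <- 1 / sqrt(1 + exp((Vm + 72.1) / 5.7))
  tau_h <- (7e-5 + 0.034 / (1 + exp((Vm + 41) / 5.5) + exp(-(Vm + 41) / 14)) +
              2e-4 / (1 + exp(-(Vm + 79) / 14))) * tm$Na_inact
  j_inf <- h_inf
  tau_j <- 10 * (7e-4 + 0.15 / (1 + exp((Vm + 41) / 5.5) + exp(-(Vm + 41) / 14)) +
                   2e-3 / (1 + exp(-(Vm + 79) / 14))) * tm$Na_inact
  i_Na <- k$g_Na * state[["m"]]^3 * state[["h"]] * state[["j"]] * (V - E_Na)

  ## late Na+ current
  m_inf_L <- 1 / (1 + exp(-(Vm + 42.85) / 5.264))
  a_mL <- 1 / (1 + exp((-60 - Vm) / 5))
  b_mL <- 0.1 / (1 + exp((Vm + 35) / 5)) + 0.1 / (1 + exp((Vm - 50) / 200))
  tau_mL <- a_mL * b_mL / 1000 * tm$NaL
  h_inf_L <- 1 / (1 + exp((Vm + k$Vh_hL) / 7.488))
  tau_hL <- k$tau_hL * tm$NaL
  i_NaL <- k$g_NaL * state[["mL"]]^3 * state[["hL"]] * (V - E_Na)

  ## funny current
  Xf_inf <- 1 / (1 + exp((Vm + 69) / 8))
  tau_Xf <- 5.6 / (1 + exp((Vm + 65) / 7) + exp(-(Vm + 65) / 19)) * tm$f
  i_fNa <- k$fNa_f * k$g_f * state[["Xf"]] * (V - E_Na)
  i_fK <- (1 - k$fNa_f) * k$g_f * state[["Xf"]] * (V - E_K)
  i_f <- i_fNa + i_fK

  ## L-type Ca2+ current (GHK driving force)
  e2 <- exp(2 * V / RTF)
  ghk <- if (abs(V) < 1e-9) 2 * F * (Cai - 0.341 * env$Cao)
         else 4 * V * F / RTF * (Cai * e2 - 0.341 * env$Cao) / (e2 - 1)
  i_CaL <- k$g_CaL * ghk * state[["d"]] * state[["f1"]] * state[["f2"]] * state[["fCa"]]

  d_inf <- 1 / (1 + exp(-(Vm + 9.1) / 7))
  a_d <- 0.25 + 1.4 / (1 + exp((-Vm - 35) / 13))
  b_d <- 1.4 / (1 + exp((Vm + 5) / 5))
  g_d <- 1 / (1 + exp((-Vm + 50) / 20))
  tau_d <- (a_d * b_d + g_d) / 1000 * tm$CaL_act

  f1_inf <- 1 / (1 + exp((Vm + 26) / 3))
  constf1 <- if (f1_inf - state[["f1"]] > 0) 1 + 1433 * (Cai - 50e-6) else 1
  tau_f1 <- (20 + 1102.5 * exp(-(((Vm + 27)^2) / 15)^2) +
               200 / (1 + exp((13 - Vm) / 10)) +
               180 / (1 + exp((30 + Vm) / 10))) * constf1 / 1000 * tm$CaL_inact
  f2_inf <- 0.33 + 0.67 / (1 + exp((Vm + 32) / 4))
  tau_f2 <- (600 * exp(-(Vm + 25)^2 / 170) + 31 / (1 + exp((25 - Vm) / 10)) +
               16 / (1 + exp((30 + Vm) / 10))) / 1000 * tm$CaL_inact
  a_fCa <- 1 / (1 + (Cai / 0.0006)^8)
  b_fCa <- 0.1 / (1 + exp((Cai - 0.0009) / 0.0001))
  g_fCa <- 0.3 / (1 + exp((Cai - 0.00075) / 0.0008))
  fCa_inf <- (a_fCa + b_fCa + g_fCa) / 1.3156
  constfCa <- if (V > -0.06 && fCa_inf > state[["fCa"]]) 0 else 1

  ## transient outward K+
  i_to <- k$g_to * (V - E_K) * state[["q"]] * state[["r"]]
  q_inf <- 1 / (1 + exp((Vm + 53) / 13))
  tau_q <- (6.06 + 39.102 / (0.57 * exp(-0.08 * (Vm + 44)) +
              0.065 * exp(0.1 * (Vm + 45.93)))) / 1000 * tm$to
  r_inf <- 1 / (1 + exp(-(Vm - 22.3) / 18.75))
  tau_r <- (2.75352 + 14.40516 / (1.037 * exp(0.09 * (Vm + 30.61)) +
              0.369 * exp(-0.12 * (Vm + 23.84)))) / 1000 * tm$to

  ## slow delayed rectifier
  i_Ks <- k$g_Ks * (V - E_Ks) * state[["Xs"]]^2 *
    (1 + 0.6 / (1 + (3.8e-5 / Cai)^1.4))
  Xs_inf <- 1 / (1 + exp((-Vm - 20) / 16))
  a_Xs <- 1100 / sqrt(1 + exp((-10 - Vm) / 6))
  b_Xs <- 1 / (1 + exp((-60 + Vm) / 20))
  tau_Xs <- a_Xs * b_Xs / 1000 * tm$Ks

  ## rapid delayed rectifier
  i_Kr <- k$g_Kr * (V - E_K) * state[["Xr1"]] * state[["Xr2"]] * sqrt(env$Ko / 5.4)
  V_half <- 1000 * (-RTF / k$Q_Kr *
    log((1 + env$Cao / 2.6)^4 / (k$L0 * (1 + env$Cao / 0.58)^4)) - 0.019)
  Xr1_inf <- 1 / (1 + exp((V_half - Vm) / 4.9))
  a_Xr1 <- 450 / (1 + exp((-45 - Vm) / 10))
  b_Xr1 <- 6 / (1 + exp((30 + Vm) / 11.5))
  tau_Xr1 <- a_Xr1 * b_Xr1 / 1000 * tm$Kr
  Xr2_inf <- 1 / (1 + exp((Vm + 88) / 50))
  a_Xr2 <- 3 / (1 + exp((-60 - Vm) / 20))
  b_Xr2 <- 1.12 / (1 + exp((-60 + Vm) / 20))
  tau_Xr2 <- a_Xr2 * b_Xr2 / 1000 * tm$Kr

  ## inward rectifier
  VEK <- Vm - E_K * 1000
  a_K1 <- 3.91 / (1 + exp(0.5942 * (VEK - 200)))
  b_K1 <- (-1.509 * exp(2e-4 * (VEK + 100)) + exp(0.5886 * (VEK - 10))) /
    (1 + exp(0.4547 * VEK))
  i_K1 <- k$g_K1 * a_K1 / (a_K1 + b_K1) * (V - E_K) * sqrt(env$Ko / 5.4)

  ## Na+/Ca2+ exchanger
  VFRT <- V / RTF
  i_NCX <- k$k_NCX *
    (exp(k$gamma_NCX * VFRT) * Nai^3 * env$Cao -
       exp((k$gamma_NCX - 1) * VFRT) * env$Nao^3 * Cai * k$alpha_NCX) /
    ((k$KmNai^3 + env$Nao^3) * (k$KmCa + env$Cao) *
       (1 + k$Ksat * exp((k$gamma_NCX - 1) * VFRT)))

  ## Na+/K+ pump
  i_NaK <- k$P_NaK * env$Ko / (env$Ko + k$Km_K) * Nai / (Nai + k$Km_Na) /
    (1 + 0.1245 * exp(-0.1 * VFRT) + 0.0353 * exp(-VFRT))

  i_PCa <- k$g_PCa * Cai / (Cai + k$KPCa)
  i_bNa <- k$g_bNa * (V - E_Na)
  i_bCa <- k$g_bCa * (V - E_Ca)

  ## SR fluxes
  i_up <- k$V_up / (1 + k$K_up^2 / Cai^2)
  i_leak <- (CaSR - Cai) * k$V_leak
  RyRSRCass <- 1 - 1 / (1 + exp((CaSR - 0.3) / 0.1))
  i_rel <- k$g_rel * RyRSRCass * state[["RyRo"]] * state[["RyRc"]] * (CaSR - Cai)

  CaiuM <- 1000 * Cai
  RyRa_inf <- k$RyRa1 - k$RyRa2 / (1 + exp((CaiuM - k$Ca_half_rel) / 0.0082))
  tau_RyRa <- k$tau_adapt_rel * tm$rel
  RyRo_inf <- 1 - 1 / (1 + exp((CaiuM - (state[["RyRa"]] + k$RyRohalf)) / 0.003))
  tau_RyRo <- (if (RyRo_inf >= state[["RyRo"]]) k$tau_act_rel
               else 0.1 * k$tau_act_rel) * tm$rel
  RyRc_inf <- 1 / (1 + exp((CaiuM - (state[["RyRa"]] + k$RyRchalf)) / 0.001))
  tau_RyRc <- (if (RyRc_inf >= state[["RyRc"]]) 2 * k$tau_inact_rel
               else k$tau_inact_rel) * tm$rel

  Cai_bufc <- 1 / (1 + k$Buf_C * k$Kbuf_C / (Cai + k$Kbuf_C)^2)
  CaSR_buf <- 1 / (1 + k$Buf_SR * k$Kbuf_SR / (CaSR + k$Kbuf_SR)^2)

  dVm <- -(i_K1 + i_to + i_Kr + i_Ks + i_CaL + i_NaK + i_Na + i_NaL +
             i_NCX + i_PCa + i_f + i_bNa + i_bCa - stim)
  d <- c(
    Vm = dVm,
    Ca_SR = CaSR_buf * k$Vc / k$V_SR * (i_up - (i_rel + i_leak)),
    Cai = Cai_bufc * (i_leak - i_up + i_rel -
            (i_CaL + i_bCa + i_PCa - 2 * i_NCX) * k$Cm / (2 * k$Vc * F * 1e-18)),
    d = (d_inf - state[["d"]]) / tau_d,
    f1 = (f1_inf - state[["f1"]]) / tau_f1,
    f2 = (f2_inf - state[["f2"]]) / tau_f2,
    fCa = constfCa * (fCa_inf - state[["fCa"]]) / 0.002,
    Xr1 = (Xr1_inf - state[["Xr1"]]) / tau_Xr1,
    Xr2 = (Xr2_inf - state[["Xr2"]]) / tau_Xr2,
    Xs = (Xs_inf - state[["Xs"]]) / tau_Xs,
    h = (h_inf - state[["h"]]) / tau_h,
    j = (j_inf - state[["j"]]) / tau_j,
    m = (m_inf - state[["m"]]) / tau_m,
    Xf = (Xf_inf - state[["Xf"]]) / tau_Xf,
    q = (q_inf - state[["q"]]) / tau_q,
    r = (r_inf - state[["r"]]) / tau_r,
    Nai = -k$Cm * (i_Na + i_NaL + i_bNa + 3 * i_NaK + 3 * i_NCX + i_fNa) /
      (F * k$Vc * 1e-18),
    mL = (m_inf_L - state[["mL"]]) / tau_mL,
    hL = (h_inf_L - state[["hL"]]) / tau_hL,
    RyRa = (RyRa_inf - state[["RyRa"]]) / tau_RyRa,
    RyRo = (RyRo_inf - state[["RyRo"]]) / tau_RyRo,
    RyRc = (RyRc_inf - state[["RyRc"]]) / tau_RyRc
  )
  list(
    derivs = d,
    currents = c(I_Na = i_Na, I_NaL = i_NaL, I_f = i_f, I_CaL = i_CaL,
                 I_to = i_to, I_Kr = i_Kr, I_Ks = i_Ks, I_K1 = i_K1,
                 I_NCX = i_NCX, I_NaK = i_NaK, I_pCa = i_PCa, I_bNa = i_bNa,
                 I_bCa = i_bCa, I_rel = i_rel, I_up = i_up, I_leak = i_leak,
                 I_stim = stim)
  )
}

# random valid states for property tests
random_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    st <- setNames(runif(22), state_names())
    st["Vm"] <- runif(1, -0.09, 0.04)
    st["Cai"] <- runif(1, 1e-5, 1e-3)
    st["Ca_SR"] <- runif(1, 0.05, 0.6)
    st["Nai"] <- runif(1, 5, 14)
    st
  })
}
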