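/* Hodgkin-Huxley-type membrane model of a ventricular-like hiPSC-CM:
 * two compartments (cytosol, SR), 22 states, 13 membrane currents + 3 SR fluxes.
 * Time in seconds, Vm in volts, concentrations in mM, currents in A/F.
 *
 * Exposed both as a deSolve compiled rhs (initmod/derivs) and as a .Call
 * entry point returning currents and derivatives for a single state.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 22
#define N_PARMS 66
#define N_CUR   17

/* state indices */
#define iVm    0
#define iCaSR  1
#define iCai   2
#define iD     3
#define iF1    4
#define iF2    5
#define iFCa   6
#define iXr1   7
#define iXr2   8
#define iXs    9
#define iH    10
#define iJ    11
#define iM    12
#define iXf   13
#define iQ    14
#define iRr   15
#define iNai  16
#define iML   17
#define iHL   18
#define iRyRa 19
#define iRyRo 20
#define iRyRc 21

/* parameter indices (order must match solver_parms() on the R side) */
enum {
  pT = 0, pNao, pKo, pCao, pKi, pCm, pVc, pVSR,
  pGNa, pGNaL, pGf, pFNaF, pGCaL, pGto, pGKs, pGKr, pGK1,
  pKNCX, pPNaK, pGpCa, pGbNa, pGbCa,
  pGrel, pVup, pVleak, pKup,
  pRyRa1, pRyRa2, pCaHalfRel, pRyRohalf, pRyRchalf,
  pTauAdaptRel, pTauActRel, pTauInactRel,
  pBufC, pBufSR, pKbufC, pKbufSR,
  pKmCa, pKmNai, pKsat, pGammaNCX, pAlphaNCX,
  pKmK, pKmNa, pKPCa, pPkNa, pL0, pQKr, pVhHL, pTauHL,
  pTmNaAct, pTmNaInact, pTmNaL, pTmCaLAct, pTmCaLInact,
  pTmKr, pTmKs, pTmTo, pTmF, pTmRel,
  pStimFlag, pStimAmp, pStimDur, pStimPeriod, pStimStart
};

#define F_CONST 96485.3415
#define R_CONST 8.314472

static double parms[N_PARMS];

void ipscpop_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

/* Evaluate all currents/fluxes (cur, A/F; SR fluxes mM/s) and state
 * derivatives (dy) at state y, time t, parameters p. */
static void cell_core(double t, const double *y, const double *p,
                      double *dy, double *cur)
{
  const double T   = p[pT];
  const double RTF = R_CONST * T / F_CONST;      /* volts */
  const double Nao = p[pNao], Ko = p[pKo], Cao = p[pCao], Ki = p[pKi];
  const double V   = y[iVm];
  const double Vm  = V * 1000.0;                  /* mV */
  const double Cai = y[iCai], CaSR = y[iCaSR], Nai = y[iNai];

  /* reversal potentials */
  const double E_Na = RTF * log(Nao / Nai);
  const double E_Ca = 0.5 * RTF * log(Cao / Cai);
  const double E_K  = RTF * log(Ko / Ki);
  const double E_Ks = RTF * log((Ko + p[pPkNa] * Nao) / (Ki + p[pPkNa] * Nai));

  /* I_Na: m^3*h*j scheme with sigmoidal steady states and bell-shaped taus */
  double m_inf = 1.0 / (1.0 + exp(-(Vm + 39.0) / 11.2));
  double tau_m = (1e-5 + 1.3e-4 * exp(-pow((Vm + 48.0) / 15.0, 2.0))
                  + 4.5e-5 / (1.0 + exp(-(Vm + 42.0) / 5.0))) * p[pTmNaAct];
  double h_inf = 1.0 / sqrt(1.0 + exp((Vm + 72.1) / 5.7));
  double tau_h = (7e-5 + 0.034 / (1.0 + exp((Vm + 41.0) / 5.5) + exp(-(Vm + 41.0) / 14.0))
                  + 2e-4 / (1.0 + exp(-(Vm + 79.0) / 14.0))) * p[pTmNaInact];
  double j_inf = h_inf;
  double tau_j = 10.0 * (7e-4 + 0.15 / (1.0 + exp((Vm + 41.0) / 5.5) + exp(-(Vm + 41.0) / 14.0))
                  + 2e-3 / (1.0 + exp(-(Vm + 79.0) / 14.0))) * p[pTmNaInact];
  double i_Na = p[pGNa] * y[iM] * y[iM] * y[iM] * y[iH] * y[iJ] * (V - E_Na);

  /* I_NaL */
  double m_inf_L  = 1.0 / (1.0 + exp(-(Vm + 42.85) / 5.264));
  double alpha_mL = 1.0 / (1.0 + exp((-60.0 - Vm) / 5.0));
  double beta_mL  = 0.1 / (1.0 + exp((Vm + 35.0) / 5.0))
                  + 0.1 / (1.0 + exp((Vm - 50.0) / 200.0));
  double tau_mL   = alpha_mL * beta_mL / 1000.0 * p[pTmNaL];
  double h_inf_L  = 1.0 / (1.0 + exp((Vm + p[pVhHL]) / 7.488));
  double tau_hL   = p[pTauHL] * p[pTmNaL];
  double i_NaL = p[pGNaL] * y[iML] * y[iML] * y[iML] * y[iHL] * (V - E_Na);

  /* I_f: Na+/K+-permeable funny current */
  double Xf_inf = 1.0 / (1.0 + exp((Vm + 69.0) / 8.0));
  double tau_Xf = 5.6 / (1.0 + exp((Vm + 65.0) / 7.0) + exp(-(Vm + 65.0) / 19.0))
                  * p[pTmF];
  double i_fNa = p[pFNaF] * p[pGf] * y[iXf] * (V - E_Na);
  double i_fK  = (1.0 - p[pFNaF]) * p[pGf] * y[iXf] * (V - E_K);
  double i_f   = i_fNa + i_fK;

  /* I_CaL: GHK driving force, d*f1*f2*fCa gating */
  double expVm2 = exp(2.0 * V / RTF);
  double ghk;
  if (fabs(V) < 1e-9) {
    /* limit of 4VF^2/RT * (Cai e^x - 0.341 Cao)/(e^x - 1) as V->0 */
    ghk = 2.0 * F_CONST * (Cai - 0.341 * Cao);
  } else {
    ghk = 4.0 * V * F_CONST / RTF * (Cai * expVm2 - 0.341 * Cao) / (expVm2 - 1.0);
  }
  double i_CaL = p[pGCaL] * ghk * y[iD] * y[iF1] * y[iF2] * y[iFCa];

  double d_inf   = 1.0 / (1.0 + exp(-(Vm + 9.1) / 7.0));
  double alpha_d = 0.25 + 1.4 / (1.0 + exp((-Vm - 35.0) / 13.0));
  double beta_d  = 1.4 / (1.0 + exp((Vm + 5.0) / 5.0));
  double gamma_d = 1.0 / (1.0 + exp((-Vm + 50.0) / 20.0));
  double tau_d   = (alpha_d * beta_d + gamma_d) / 1000.0 * p[pTmCaLAct];

  double f1_inf = 1.0 / (1.0 + exp((Vm + 26.0) / 3.0));
  double constf1 = (f1_inf - y[iF1] > 0.0) ? (1.0 + 1433.0 * (Cai - 50.0e-6)) : 1.0;
  double tau_f1 = (20.0 + 1102.5 * exp(-pow(pow(Vm + 27.0, 2.0) / 15.0, 2.0))
                   + 200.0 / (1.0 + exp((13.0 - Vm) / 10.0))
                   + 180.0 / (1.0 + exp((30.0 + Vm) / 10.0)))
                  * constf1 / 1000.0 * p[pTmCaLInact];

  double f2_inf = 0.33 + 0.67 / (1.0 + exp((Vm + 32.0) / 4.0));
  double tau_f2 = (600.0 * exp(-pow(Vm + 25.0, 2.0) / 170.0)
                   + 31.0 / (1.0 + exp((25.0 - Vm) / 10.0))
                   + 16.0 / (1.0 + exp((30.0 + Vm) / 10.0))) / 1000.0 * p[pTmCaLInact];

  double alpha_fCa = 1.0 / (1.0 + pow(Cai / 0.0006, 8.0));
  double beta_fCa  = 0.1 / (1.0 + exp((Cai - 0.0009) / 0.0001));
  double gamma_fCa = 0.3 / (1.0 + exp((Cai - 0.00075) / 0.0008));
  double fCa_inf   = (alpha_fCa + beta_fCa + gamma_fCa) / 1.3156;
  double constfCa  = (V > -0.06 && fCa_inf > y[iFCa]) ? 0.0 : 1.0;
  double tau_fCa   = 0.002;

  /* I_to */
  double i_to  = p[pGto] * (V - E_K) * y[iQ] * y[iRr];
  double q_inf = 1.0 / (1.0 + exp((Vm + 53.0) / 13.0));
  double tau_q = (6.06 + 39.102 / (0.57 * exp(-0.08 * (Vm + 44.0))
                   + 0.065 * exp(0.1 * (Vm + 45.93)))) / 1000.0 * p[pTmTo];
  double r_inf = 1.0 / (1.0 + exp(-(Vm - 22.3) / 18.75));
  double tau_r = (2.75352 + 14.40516 / (1.037 * exp(0.09 * (Vm + 30.61))
                   + 0.369 * exp(-0.12 * (Vm + 23.84)))) / 1000.0 * p[pTmTo];

  /* I_Ks with Cai-dependent augmentation */
  double i_Ks = p[pGKs] * (V - E_Ks) * y[iXs] * y[iXs]
                * (1.0 + 0.6 / (1.0 + pow(3.8e-5 / Cai, 1.4)));
  double Xs_inf   = 1.0 / (1.0 + exp((-Vm - 20.0) / 16.0));
  double alpha_Xs = 1100.0 / sqrt(1.0 + exp((-10.0 - Vm) / 6.0));
  double beta_Xs  = 1.0 / (1.0 + exp((-60.0 + Vm) / 20.0));
  double tau_Xs   = alpha_Xs * beta_Xs / 1000.0 * p[pTmKs];

  /* I_Kr; Xr1 half-activation depends on Cao */
  double i_Kr = p[pGKr] * (V - E_K) * y[iXr1] * y[iXr2] * sqrt(Ko / 5.4);
  double V_half = 1000.0 * (-RTF / p[pQKr]
                  * log(pow(1.0 + Cao / 2.6, 4.0) / (p[pL0] * pow(1.0 + Cao / 0.58, 4.0)))
                  - 0.019);
  double Xr1_inf   = 1.0 / (1.0 + exp((V_half - Vm) / 4.9));
  double alpha_Xr1 = 450.0 / (1.0 + exp((-45.0 - Vm) / 10.0));
  double beta_Xr1  = 6.0 / (1.0 + exp((30.0 + Vm) / 11.5));
  double tau_Xr1   = alpha_Xr1 * beta_Xr1 / 1000.0 * p[pTmKr];
  double Xr2_inf   = 1.0 / (1.0 + exp((Vm + 88.0) / 50.0));
  double alpha_Xr2 = 3.0 / (1.0 + exp((-60.0 - Vm) / 20.0));
  double beta_Xr2  = 1.12 / (1.0 + exp((-60.0 + Vm) / 20.0));
  double tau_Xr2   = alpha_Xr2 * beta_Xr2 / 1000.0 * p[pTmKr];

  /* I_K1 (instantaneous) */
  double VEK = Vm - E_K * 1000.0;
  double alpha_K1 = 3.91 / (1.0 + exp(0.5942 * (VEK - 200.0)));
  double beta_K1  = (-1.509 * exp(0.0002 * (VEK + 100.0)) + exp(0.5886 * (VEK - 10.0)))
                    / (1.0 + exp(0.4547 * VEK));
  double XK1_inf  = alpha_K1 / (alpha_K1 + beta_K1);
  double i_K1 = p[pGK1] * XK1_inf * (V - E_K) * sqrt(Ko / 5.4);

  /* I_NCX */
  double VFRT = V / RTF;
  double i_NCX = p[pKNCX]
    * (exp(p[pGammaNCX] * VFRT) * Nai * Nai * Nai * Cao
       - exp((p[pGammaNCX] - 1.0) * VFRT) * Nao * Nao * Nao * Cai * p[pAlphaNCX])
    / ((pow(p[pKmNai], 3.0) + Nao * Nao * Nao) * (p[pKmCa] + Cao)
       * (1.0 + p[pKsat] * exp((p[pGammaNCX] - 1.0) * VFRT)));

  /* I_NaK */
  double i_NaK = p[pPNaK] * Ko / (Ko + p[pKmK]) * Nai / (Nai + p[pKmNa])
    / (1.0 + 0.1245 * exp(-0.1 * VFRT) + 0.0353 * exp(-VFRT));

  /* I_pCa, backgrounds */
  double i_PCa = p[pGpCa] * Cai / (Cai + p[pKPCa]);
  double i_bNa = p[pGbNa] * (V - E_Na);
  double i_bCa = p[pGbCa] * (V - E_Ca);

  /* SR fluxes */
  double i_up   = p[pVup] / (1.0 + p[pKup] * p[pKup] / (Cai * Cai));
  double i_leak = (CaSR - Cai) * p[pVleak];

  double RyRSRCass = 1.0 - 1.0 / (1.0 + exp((CaSR - 0.3) / 0.1));
  double i_rel = p[pGrel] * RyRSRCass * y[iRyRo] * y[iRyRc] * (CaSR - Cai);

  double CaiuM = 1000.0 * Cai;  /* uM */
  double RyRa_inf = p[pRyRa1] - p[pRyRa2] / (1.0 + exp((CaiuM - p[pCaHalfRel]) / 0.0082));
  double tau_RyRa = p[pTauAdaptRel] * p[pTmRel];
  double RyRo_inf = 1.0 - 1.0 / (1.0 + exp((CaiuM - (y[iRyRa] + p[pRyRohalf])) / 0.003));
  double tau_RyRo = ((RyRo_inf >= y[iRyRo]) ? p[pTauActRel] : 0.1 * p[pTauActRel])
                    * p[pTmRel];
  double RyRc_inf = 1.0 / (1.0 + exp((CaiuM - (y[iRyRa] + p[pRyRchalf])) / 0.001));
  double tau_RyRc = ((RyRc_inf >= y[iRyRc]) ? 2.0 * p[pTauInactRel] : p[pTauInactRel])
                    * p[pTmRel];

  /* instantaneous Ca2+ buffering */
  double Cai_bufc = 1.0 / (1.0 + p[pBufC] * p[pKbufC] / pow(Cai + p[pKbufC], 2.0));
  double CaSR_buf = 1.0 / (1.0 + p[pBufSR] * p[pKbufSR] / pow(CaSR + p[pKbufSR], 2.0));

  /* stimulus */
  double i_stim = 0.0;
  if (p[pStimFlag] > 0.5 && t >= p[pStimStart]) {
    double tt = fmod(t - p[pStimStart], p[pStimPeriod]);
    if (tt <= p[pStimDur]) i_stim = p[pStimAmp];
  }

  /* derivatives */
  dy[iVm] = -(i_K1 + i_to + i_Kr + i_Ks + i_CaL + i_NaK + i_Na + i_NaL
              + i_NCX + i_PCa + i_f + i_bNa + i_bCa - i_stim);
  dy[iCaSR] = CaSR_buf * p[pVc] / p[pVSR] * (i_up - (i_rel + i_leak));
  dy[iCai]  = Cai_bufc * (i_leak - i_up + i_rel
              - (i_CaL + i_bCa + i_PCa - 2.0 * i_NCX) * p[pCm]
                / (2.0 * p[pVc] * F_CONST * 1.0e-18));
  dy[iD]   = (d_inf - y[iD]) / tau_d;
  dy[iF1]  = (f1_inf - y[iF1]) / tau_f1;
  dy[iF2]  = (f2_inf - y[iF2]) / tau_f2;
  dy[iFCa] = constfCa * (fCa_inf - y[iFCa]) / tau_fCa;
  dy[iXr1] = (Xr1_inf - y[iXr1]) / tau_Xr1;
  dy[iXr2] = (Xr2_inf - y[iXr2]) / tau_Xr2;
  dy[iXs]  = (Xs_inf - y[iXs]) / tau_Xs;
  dy[iH]   = (h_inf - y[iH]) / tau_h;
  dy[iJ]   = (j_inf - y[iJ]) / tau_j;
  dy[iM]   = (m_inf - y[iM]) / tau_m;
  dy[iXf]  = (Xf_inf - y[iXf]) / tau_Xf;
  dy[iQ]   = (q_inf - y[iQ]) / tau_q;
  dy[iRr]  = (r_inf - y[iRr]) / tau_r;
  dy[iNai] = -p[pCm] * (i_Na + i_NaL + i_bNa + 3.0 * i_NaK + 3.0 * i_NCX + i_fNa)
             / (F_CONST * p[pVc] * 1.0e-18);
  dy[iML]  = (m_inf_L - y[iML]) / tau_mL;
  dy[iHL]  = (h_inf_L - y[iHL]) / tau_hL;
  dy[iRyRa] = (RyRa_inf - y[iRyRa]) / tau_RyRa;
  dy[iRyRo] = (RyRo_inf - y[iRyRo]) / tau_RyRo;
  dy[iRyRc] = (RyRc_inf - y[iRyRc]) / tau_RyRc;

  if (cur) {
    cur[0]  = i_Na;  cur[1]  = i_NaL; cur[2]  = i_f;   cur[3]  = i_CaL;
    cur[4]  = i_to;  cur[5]  = i_Kr;  cur[6]  = i_Ks;  cur[7]  = i_K1;
    cur[8]  = i_NCX; cur[9]  = i_NaK; cur[10] = i_PCa; cur[11] = i_bNa;
    cur[12] = i_bCa; cur[13] = i_rel; cur[14] = i_up;  cur[15] = i_leak;
    cur[16] = i_stim;
  }
}

/* deSolve derivative callback */
void ipscpop_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
  double cur[N_CUR];
  cell_core(*t, y, parms, ydot, cur);
  if (*ip >= N_CUR) {
    for (int k = 0; k < N_CUR; k++) yout[k] = cur[k];
  }
}

/* single-state evaluation from R: returns list(derivatives, currents) */
SEXP C_cell_eval(SEXP state, SEXP pars, SEXP time)
{
  if (LENGTH(state) != N_STATE) error("state must have %d entries", N_STATE);
  if (LENGTH(pars) != N_PARMS) error("parameter vector must have %d entries", N_PARMS);
  double dy[N_STATE], cur[N_CUR];
  cell_core(REAL(time)[0], REAL(state), REAL(pars), dy, cur);
  SEXP ans = PROTECT(allocVector(VECSXP, 2));
  SEXP sdy = PROTECT(allocVector(REALSXP, N_STATE));
  SEXP scur = PROTECT(allocVector(REALSXP, N_CUR));
  for (int k = 0; k < N_STATE; k++) REAL(sdy)[k] = dy[k];
  for (int k = 0; k < N_CUR; k++) REAL(scur)[k] = cur[k];
  SET_VECTOR_ELT(ans, 0, sdy);
  SET_VECTOR_ELT(ans, 1, scur);
  UNPROTECT(3);
  return ans;
}

static const R_CallMethodDef callMethods[] = {
  {"C_cell_eval", (DL_FUNC) &C_cell_eval, 3},
  {NULL, NULL, 0}
};

void R_init_ipscpop(DllInfo *info)
{
  R_registerRoutines(info, NULL, callMethods, NULL, NULL);
  R_useDynamicSymbols(info, TRUE);  /* deSolve looks up ipscpop_derivs by name */
}
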