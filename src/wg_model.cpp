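// Rabbit ventricular myocyte model in the Shannon-Bers family, with a
// two-compartment submembrane space (junctional cleft JXN + subsarcolemmal
// SL), junctional/network SR, 4-state Markov RyR gating with luminal
// regulation, and GHK L-type Ca current whose voltage-dependent steady-state
// inactivation f_ss is non-monotonic (late rise at positive voltages).
// Explicit-Euler integration; voltage/Ca/current clamps are honored inside
// the step so that a clamped current is substituted in both the voltage
// equation and the ion-flux equations.
//
// Units: time ms, voltage mV, concentrations mM, currents A/F,
// volumes liters.  Intracellular Na+ and K+ are fixed parameters.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------- physical constants and geometry ----------
static const double FARADAY = 96485.0;   // C/mol
static const double RGAS    = 8314.0;    // mJ/(mol K)

static const double VCELL = 3.3e-11;              // l
static const double VMYO  = 0.65   * VCELL;
static const double VSR   = 0.035  * VCELL;
static const double VJSR  = 0.10   * VSR;
static const double VNSR  = 0.90   * VSR;
static const double VSL   = 0.02   * VCELL;
static const double VJXN  = 5.39e-4 * VCELL;
static const double CMEM  = 1.381e-10;            // F

// cytosolic Ca buffers (rapid equilibrium): troponin-C, calmodulin, SR sites
static const double BTNC = 0.070,  KTNC = 6.0e-4;
static const double BCAM = 0.024,  KCAM = 7.0e-3;
static const double BSRB = 0.0171, KSRB = 8.7e-4;
// submembrane sarcolemmal sites, low/high affinity, per compartment volume
static const double BSLL_J = 0.554,  KSLL = 1.3e-2;
static const double BSLH_J = 0.199,  KSLH = 3.0e-4;
static const double BSLL_S = 1.216;
static const double BSLH_S = 0.436;
// calsequestrin in JSR
static const double BCSQN = 26.0, KCSQN = 0.65;

// ---------- state vector layout ----------
enum StateIdx {
  iV = 0, iM, iH, iJ, iD, iF, iFCAJ, iFCASL, iXTO, iYTO, iXKR, iXKS,
  iRYR_R, iRYR_O, iRYR_I, iCAJ, iCASL, iCAI, iCAJSR, iCANSR, NSTATE
};

// ---------- parameter vector layout (kept in step with R/model.R) ----------
enum ParIdx {
  pKMAX = 0, pJCASLMYO, pPCA, pGKS, pINCXBAR,
  pGNA, pGNAB, pGCAB, pGTOF, pGKR, pGK1, pINAKBAR, pIPCABAR,
  pVMAXUP, pKMF, pKMR, pHUP, pTAUTR, pKLEAK, pJCAJUNCSL,
  pNAI, pKI, pNAO, pKO, pCAO, pTEMP,
  pKOCA, pKOM, pKICA, pKIM, pEC50SR, pMAXSR, pMINSR,
  pKDACT, pKMCAI, pKMCAO, pKMNAI, pKMNAO, pKSAT, pNU,
  pKMNAIP, pKMKO, pPNAK, pFJUNC, pFJCAL,
  pTAUXS_SCALE, pTAUF_SCALE, pKFCA, pHOCA, pFSSVH, pFSSSL,
  pFSSFLAT, pBLOCKCATM, NPAR
};

struct Snapshot {
  double INa, INab, ICaL_j, ICaL_sl, ICab_j, ICab_sl, IpCa_j, IpCa_sl;
  double Ito, IKr, IKs_j, IKs_sl, IK1, INaK, INCX_j, INCX_sl;
  double Iion, Isti;
  double dss, taud, fss, tauf, fca_j, fca_sl;
  double Jrel, Jup, Jtr, Jleak;
};

// steady-state voltage inactivation of I_CaL; the second term produces the
// late rise ("non-monotonic f_ss"); flattened variant holds the minimum
static inline double fss_raw(double v, double vh, double sl) {
  double f = 1.0 / (1.0 + exp((v + vh) / sl)) +
             0.6 / (1.0 + exp((50.0 - v) / 20.0));
  return (f > 1.0) ? 1.0 : f;   // the two-term sum slightly exceeds 1 at rest
}

static void fss_find_min(double vh, double sl, double *vstar, double *fmin) {
  double best = 1e9, vb = 0.0;
  for (double v = -90.0; v <= 70.0; v += 0.01) {
    double f = fss_raw(v, vh, sl);
    if (f < best) { best = f; vb = v; }
  }
  *vstar = vb;
  *fmin = best;
}

static inline double fss_eval(double v, const double *p,
                              double vstar, double fmin) {
  if (!(p[pFSSFLAT] > 0.5)) return fss_raw(v, p[pFSSVH], p[pFSSSL]);
  return (v <= vstar) ? fss_raw(v, p[pFSSVH], p[pFSSSL]) : fmin;
}

// full right-hand side; clampV/clampCa substitute values before evaluation,
// clamped currents are substituted after free evaluation via caller-supplied
// totals (<0 = free) and re-split by the free-running compartment shares.
static void rhs(const double *s, const double *p, double Isti,
                double *ds, Snapshot *sn,
                bool clampCa, bool clampV,
                bool clampICaL, double ICaL_target,
                bool clampINCX, double INCX_target,
                double fss_vstar = 0.0, double fss_min = 0.0) {
  const double V = s[iV];
  const double T = p[pTEMP];
  const double FRT = FARADAY / (RGAS * T);      // 1/mV
  const double Nai = p[pNAI], Ki = p[pKI];
  const double Nao = p[pNAO], Ko = p[pKO], Cao = p[pCAO];

  const double ENa = log(Nao / Nai) / FRT;
  const double EK  = log(Ko / Ki) / FRT;
  const double EKs = log((Ko + p[pPNAK] * Nao) / (Ki + p[pPNAK] * Nai)) / FRT;

  const double Caj = s[iCAJ], Casl = s[iCASL], Cai = s[iCAI];
  const double Cajsr = s[iCAJSR], Cansr = s[iCANSR];
  const double Fj = p[pFJUNC], Fsl = 1.0 - Fj;
  const double FjCaL = p[pFJCAL], FslCaL = 1.0 - FjCaL;

  // ----- fast Na current (Luo-Rudy kinetics) -----
  double am = (fabs(V + 47.13) < 1e-6) ? 3.2
              : 0.32 * (V + 47.13) / (1.0 - exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + exp((V + 10.66) / (-11.1))));
    aj = 0.0;
    bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * exp((80.0 + V) / (-6.8));
    bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
    aj = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  const double m = s[iM], h = s[iH], jg = s[iJ];
  double INa = p[pGNA] * m * m * m * h * jg * (V - ENa);
  double INab = p[pGNAB] * (V - ENa);

  // gating relaxation rates are floored (tau >= TAU_MIN) so that the
  // reference explicit-Euler step of 0.01 ms stays inside the stability
  // region of every gate; the floor only binds for the Na activation gate
  // near rest, where m is already at its tiny steady state
  const double TAU_MIN = 0.3;
  double mss = am / (am + bm), taum = std::max(1.0 / (am + bm), TAU_MIN);
  double hss = ah / (ah + bh), tauh = std::max(1.0 / (ah + bh), TAU_MIN);
  double jss = aj / (aj + bj), taujj = std::max(1.0 / (aj + bj), TAU_MIN);

  // ----- L-type Ca current (GHK), junctional + subsarcolemmal -----
  double dss = 1.0 / (1.0 + exp(-(V + 14.5) / 6.0));
  double taud;
  if (fabs(V + 14.5) < 1e-6) taud = 1.0 / (0.035 * 6.0);
  else taud = dss * (1.0 - exp(-(V + 14.5) / 6.0)) / (0.035 * (V + 14.5));
  double fss = fss_eval(V, p, fss_vstar, fss_min);
  double tauf = p[pTAUF_SCALE] /
      (0.0197 * exp(-pow(0.0337 * (V + 14.5), 2.0)) + 0.02);

  double x = 2.0 * V * FRT;
  // A/F per (cm/s of permeability); 0.341 = divalent activity coefficient
  double pref = p[pPCA] * 2.0 * FARADAY;
  double ghk_j, ghk_sl;
  if (fabs(x) < 1e-6) {
    ghk_j  = pref * (0.341 * Caj  - 0.341 * Cao);
    ghk_sl = pref * (0.341 * Casl - 0.341 * Cao);
  } else {
    double e = exp(x), den = e - 1.0;
    ghk_j  = pref * x * (0.341 * Caj  * e - 0.341 * Cao) / den;
    ghk_sl = pref * x * (0.341 * Casl * e - 0.341 * Cao) / den;
  }
  const double d = s[iD], f = s[iF];
  const double fca_j  = 1.0 - s[iFCAJ];
  const double fca_sl = 1.0 - s[iFCASL];
  double ICaL_j  = FjCaL  * ghk_j  * d * f * fca_j;
  double ICaL_sl = FslCaL * ghk_sl * d * f * fca_sl;

  // ----- transient outward K current (fast component) -----
  double xtoss = 1.0 / (1.0 + exp(-(V - 19.0) / 13.0));
  double tauxto = 8.5 * exp(-pow((V + 45.0) / 50.0, 2.0)) + 0.5;
  double ytoss = 1.0 / (1.0 + exp((V + 19.5) / 5.0));
  double tauyto = 85.0 * exp(-pow(V + 40.0, 2.0) / 220.0) + 4.5;
  double Ito = p[pGTOF] * s[iXTO] * s[iYTO] * (V - EK);

  // ----- rapid delayed rectifier -----
  double xrss = 1.0 / (1.0 + exp(-(V + 50.0) / 7.5));
  double tauxr = 1.0 /
      (1.38e-3 * ((fabs(V + 7.0) < 1e-6) ? 1.0 / 0.123
                  : (V + 7.0) / (1.0 - exp(-0.123 * (V + 7.0)))) +
       6.1e-4 * ((fabs(V + 10.0) < 1e-6) ? 1.0 / 0.145
                  : (V + 10.0) / (exp(0.145 * (V + 10.0)) - 1.0)));
  double rkr = 1.0 / (1.0 + exp((V + 33.0) / 22.4));
  double IKr = p[pGKR] * sqrt(Ko / 5.4) * s[iXKR] * rkr * (V - EK);

  // ----- slow delayed rectifier (split by compartment share) -----
  double xsss = 1.0 / (1.0 + exp(-(V - 1.5) / 16.7));
  double tauxs = p[pTAUXS_SCALE] /
      (7.19e-5 * ((fabs(V + 30.0) < 1e-6) ? 1.0 / 0.148
                  : (V + 30.0) / (1.0 - exp(-0.148 * (V + 30.0)))) +
       1.31e-4 * ((fabs(V + 30.0) < 1e-6) ? 1.0 / 0.0687
                  : (V + 30.0) / (exp(0.0687 * (V + 30.0)) - 1.0)));
  double xks = s[iXKS];
  double IKs_tot = p[pGKS] * xks * xks * (V - EKs);
  double IKs_j = Fj * IKs_tot, IKs_sl = Fsl * IKs_tot;

  // ----- inward rectifier -----
  double dvk = V - EK;
  double aK1 = 1.02 / (1.0 + exp(0.2385 * (dvk - 59.215)));
  double bK1 = (0.49124 * exp(0.08032 * (dvk + 5.476)) +
                exp(0.06175 * (dvk - 594.31))) /
               (1.0 + exp(-0.5143 * (dvk + 4.753)));
  double IK1 = p[pGK1] * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * dvk;

  // ----- Na/K pump -----
  double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V * FRT) +
                       0.0365 * sigma * exp(-V * FRT));
  double INaK = p[pINAKBAR] * fnak * Ko /
      ((1.0 + pow(p[pKMNAIP] / Nai, 4.0)) * (Ko + p[pKMKO]));

  // ----- Na/Ca exchanger, per submembrane compartment -----
  double Nai3 = Nai * Nai * Nai, Nao3 = Nao * Nao * Nao;
  double expnu  = exp(p[pNU] * V * FRT);
  double expnu1 = exp((p[pNU] - 1.0) * V * FRT);
  double satfac = 1.0 + p[pKSAT] * expnu1;
  double KmCai = p[pKMCAI], KmCao = p[pKMCAO];
  double KmNai = p[pKMNAI], KmNao3 = pow(p[pKMNAO], 3.0);
  double ncx_term = KmCai * Nao3 * (1.0 + pow(Nai / KmNai, 3.0)) +
                    KmCao * Nai3;
  auto ncx = [&](double Ca) {
    double Ka = 1.0 / (1.0 + pow(p[pKDACT] / Ca, 2.0));
    double s1 = expnu * Nai3 * Cao;
    double s2 = expnu1 * Nao3 * Ca;
    double den = (ncx_term + KmNao3 * Ca * (1.0 + Ca / KmCai) +
                  Nai3 * Cao + Nao3 * Ca) * satfac;
    return p[pINCXBAR] * Ka * (s1 - s2) / den;
  };
  double INCX_j  = Fj  * ncx(Caj);
  double INCX_sl = Fsl * ncx(Casl);

  // ----- sarcolemmal Ca pump and background Ca current -----
  auto ipca = [&](double Ca) {
    double c = pow(Ca, 1.6);
    return p[pIPCABAR] * c / (pow(5.0e-4, 1.6) + c);
  };
  double IpCa_j = Fj * ipca(Caj), IpCa_sl = Fsl * ipca(Casl);
  double ECa_j  = 0.5 * log(Cao / Caj) / FRT;
  double ECa_sl = 0.5 * log(Cao / Casl) / FRT;
  double ICab_j  = Fj  * p[pGCAB] * (V - ECa_j);
  double ICab_sl = Fsl * p[pGCAB] * (V - ECa_sl);

  // ----- substitute clamped currents (voltage AND flux equations) -----
  if (clampICaL) {
    double tot = ICaL_j + ICaL_sl;
    if (fabs(tot) > 1e-9) {
      double fac = ICaL_target / tot;
      ICaL_j *= fac; ICaL_sl *= fac;
    } else {
      ICaL_j = FjCaL * ICaL_target; ICaL_sl = FslCaL * ICaL_target;
    }
  }
  if (clampINCX) {
    double tot = INCX_j + INCX_sl;
    if (fabs(tot) > 1e-9) {
      double fac = INCX_target / tot;
      INCX_j *= fac; INCX_sl *= fac;
    } else {
      INCX_j = Fj * INCX_target; INCX_sl = Fsl * INCX_target;
    }
  }

  bool blockCaTM = p[pBLOCKCATM] > 0.5;
  double ICaL_j_f = ICaL_j, ICaL_sl_f = ICaL_sl;
  double ICab_j_f = ICab_j, ICab_sl_f = ICab_sl;
  double IpCa_j_f = IpCa_j, IpCa_sl_f = IpCa_sl;
  double INCX_j_f = INCX_j, INCX_sl_f = INCX_sl;
  if (blockCaTM) {
    ICaL_j = ICaL_sl = ICab_j = ICab_sl = IpCa_j = IpCa_sl = 0.0;
    INCX_j = INCX_sl = 0.0;
    ICaL_j_f = ICaL_sl_f = ICab_j_f = ICab_sl_f = 0.0;
    IpCa_j_f = IpCa_sl_f = INCX_j_f = INCX_sl_f = 0.0;
  }

  double Iion = INa + INab + ICaL_j + ICaL_sl + ICab_j + ICab_sl +
                IpCa_j + IpCa_sl + Ito + IKr + IKs_j + IKs_sl + IK1 +
                INaK + INCX_j + INCX_sl;

  // ----- SR fluxes -----
  double kCaSR = p[pMAXSR] - (p[pMAXSR] - p[pMINSR]) /
      (1.0 + pow(p[pEC50SR] / Cajsr, 2.5));
  double koSRCa = p[pKOCA] / kCaSR;
  double kiSRCa = p[pKICA] * kCaSR;
  double rR = s[iRYR_R], rO = s[iRYR_O], rI = s[iRYR_I];
  double rRI = 1.0 - rR - rO - rI;

  // release flux referenced to the junctional volume with the SR-to-cleft
  // volume gain, so that the control k_max of 0.2 ms^-1 yields a full CICR
  // transient at sub-unity RyR open fractions
  const double GREL = VSR / VJXN;
  double Jrel  = p[pKMAX] * rO * (Cajsr - Caj) * GREL;  // mM/ms (JXN vol)
  double Jleak = p[pKLEAK] * (Cajsr - Caj) * GREL;      // mM/ms (JXN vol)
  double hup = p[pHUP];
  double up_f = pow(Cai / p[pKMF], hup), up_r = pow(Cansr / p[pKMR], hup);
  double Jup = p[pVMAXUP] * (up_f - up_r) / (1.0 + up_f + up_r); // mM/ms (cyto vol)
  double Jtr = (Cansr - Cajsr) / p[pTAUTR];             // mM/ms (JSR vol)

  // inter-compartment diffusion (mmol/ms)
  double Jjsl   = p[pJCAJUNCSL] * (Caj - Casl);
  double Jslmyo = p[pJCASLMYO] * (Casl - Cai);

  // ----- buffering factors (rapid equilibrium) -----
  auto beta2 = [](double Ca, double B1, double K1c, double B2, double K2c) {
    double d1 = K1c + Ca, d2 = K2c + Ca;
    return 1.0 / (1.0 + B1 * K1c / (d1 * d1) + B2 * K2c / (d2 * d2));
  };
  double bi = 1.0 / (1.0 +
      BTNC * KTNC / ((KTNC + Cai) * (KTNC + Cai)) +
      BCAM * KCAM / ((KCAM + Cai) * (KCAM + Cai)) +
      BSRB * KSRB / ((KSRB + Cai) * (KSRB + Cai)));
  double bj2 = beta2(Caj, BSLL_J, KSLL, BSLH_J, KSLH);
  double bsl = beta2(Casl, BSLL_S, KSLL, BSLH_S, KSLH);
  double bjsr = 1.0 / (1.0 +
      BCSQN * KCSQN / ((KCSQN + Cajsr) * (KCSQN + Cajsr)));

  // ----- derivatives -----
  for (int k = 0; k < NSTATE; ++k) ds[k] = 0.0;

  ds[iV] = -Iion + Isti;
  ds[iM] = (mss - m) / taum;
  ds[iH] = (hss - h) / tauh;
  ds[iJ] = (jss - jg) / taujj;
  ds[iD] = (dss - d) / taud;
  ds[iF] = (fss - f) / tauf;
  ds[iFCAJ]  = p[pKFCA] * Caj  * (1.0 - s[iFCAJ])  - 11.9e-3 * s[iFCAJ];
  ds[iFCASL] = p[pKFCA] * Casl * (1.0 - s[iFCASL]) - 11.9e-3 * s[iFCASL];
  ds[iXTO] = (xtoss - s[iXTO]) / tauxto;
  ds[iYTO] = (ytoss - s[iYTO]) / tauyto;
  ds[iXKR] = (xrss - s[iXKR]) / tauxr;
  ds[iXKS] = (xsss - xks) / tauxs;

  // transition rates capped at 5 ms^-1: keeps the Markov chain inside the
  // explicit-Euler stability region during the largest cleft Ca spikes
  double CajH = pow(Caj, p[pHOCA]);
  double r_open = std::min(koSRCa * CajH, 5.0);
  double r_inac = std::min(kiSRCa * Caj, 5.0);
  ds[iRYR_R] = p[pKIM] * rRI - r_inac * rR - (r_open * rR - p[pKOM] * rO);
  ds[iRYR_O] = r_open * rR - p[pKOM] * rO - (r_inac * rO - p[pKIM] * rI);
  ds[iRYR_I] = r_inac * rO - p[pKIM] * rI - (p[pKOM] * rI - r_open * rRI);

  double camem_j = -(ICaL_j_f + ICab_j_f + IpCa_j_f - 2.0 * INCX_j_f) *
                   CMEM / (2.0 * FARADAY * VJXN);
  double camem_sl = -(ICaL_sl_f + ICab_sl_f + IpCa_sl_f - 2.0 * INCX_sl_f) *
                    CMEM / (2.0 * FARADAY * VSL);

  ds[iCAJ]  = bj2 * (camem_j + Jrel + Jleak - Jjsl / VJXN);
  ds[iCASL] = bsl * (camem_sl + Jjsl / VSL - Jslmyo / VSL);
  ds[iCAI]  = bi  * (Jslmyo / VMYO - Jup);
  ds[iCAJSR] = bjsr * (Jtr - (Jrel + Jleak) * VJXN / VJSR);
  ds[iCANSR] = Jup * VMYO / VNSR - Jtr * VJSR / VNSR;

  if (clampV)  ds[iV] = 0.0;
  if (clampCa) { ds[iCAJ] = 0.0; ds[iCASL] = 0.0; }

  if (sn) {
    sn->INa = INa; sn->INab = INab;
    sn->ICaL_j = ICaL_j; sn->ICaL_sl = ICaL_sl;
    sn->ICab_j = ICab_j; sn->ICab_sl = ICab_sl;
    sn->IpCa_j = IpCa_j; sn->IpCa_sl = IpCa_sl;
    sn->Ito = Ito; sn->IKr = IKr; sn->IKs_j = IKs_j; sn->IKs_sl = IKs_sl;
    sn->IK1 = IK1; sn->INaK = INaK;
    sn->INCX_j = INCX_j; sn->INCX_sl = INCX_sl;
    sn->Iion = Iion; sn->Isti = Isti;
    sn->dss = dss; sn->taud = taud; sn->fss = fss; sn->tauf = tauf;
    sn->fca_j = fca_j; sn->fca_sl = fca_sl;
    sn->Jrel = Jrel; sn->Jup = Jup; sn->Jtr = Jtr; sn->Jleak = Jleak;
  }
}

// ---------- clamp bookkeeping ----------
struct Clamp {
  bool active_any = false;
  int mode = 0;          // 0 constant, 1 scaled trace, 2 linear ramp
  double value = NA_REAL;
  double end_value = NA_REAL;
  double scale = 1.0;
  double t_on = 0.0, t_off = 0.0;
  double ref_t0 = 0.0, ref_dt = 1.0;
  NumericVector ref;
  bool captured = false; // constant/ramp start level captured at t_on
  double captured_value = NA_REAL;

  bool active(double t) const {
    return active_any && t >= t_on && t < t_off;
  }
  double interp(double t) const {
    double u = (t - ref_t0) / ref_dt;
    int n = ref.size();
    if (u <= 0.0) return ref[0];
    int k = (int)u;
    if (k >= n - 1) return ref[n - 1];
    double w = u - k;
    return (1.0 - w) * ref[k] + w * ref[k + 1];
  }
  double level(double t, double freeval) {
    switch (mode) {
      case 0:
        if (!R_finite(value)) {
          if (!captured) { captured = true; captured_value = freeval; }
          return captured_value;
        }
        return value;
      case 1:
        return scale * interp(t);
      default: {  // ramp from level at t_on to end_value at t_off
        if (!captured) { captured = true; captured_value = freeval; }
        double w = (t - t_on) / (t_off - t_on);
        return captured_value + w * (end_value - captured_value);
      }
    }
  }
};

static Clamp parse_clamp(List cl) {
  Clamp c;
  c.active_any = true;
  c.mode = as<int>(cl["mode"]);
  c.value = as<double>(cl["value"]);
  c.end_value = as<double>(cl["end_value"]);
  c.scale = as<double>(cl["scale"]);
  c.t_on = as<double>(cl["t_on"]);
  c.t_off = as<double>(cl["t_off"]);
  if (c.mode == 1) {
    c.ref = as<NumericVector>(cl["ref"]);
    c.ref_t0 = as<double>(cl["ref_t0"]);
    c.ref_dt = as<double>(cl["ref_dt"]);
  }
  return c;
}

// columns stored in the trace
enum TraceCol {
  cT = 0, cV, cCASUB, cCAJ, cCASL, cCAI, cCAJSR, cCANSR,
  cICAL, cINCX, cIKS, cISTI, cRYRO, NTRACECOL
};

//' @noRd
// [[Rcpp::export(name = ".wg_integrate_cpp")]]
List wg_integrate_cpp(NumericVector params, NumericVector state0,
                      double t_end, double dt, int stride,
                      NumericVector stim_starts, double stim_amp,
                      double stim_dur, List clamps,
                      bool stop_at_repol, double repol_threshold) {
  if (params.size() != NPAR) stop("parameter vector has wrong length");
  if (state0.size() != NSTATE) stop("state vector has wrong length");
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive");

  Clamp clCa, clV, clICaL, clINCX;
  CharacterVector tg;
  if (clamps.size() > 0) {
    for (int i = 0; i < clamps.size(); ++i) {
      List cl = clamps[i];
      std::string target = as<std::string>(cl["target"]);
      if (target == "Ca_sub") clCa = parse_clamp(cl);
      else if (target == "V_m") clV = parse_clamp(cl);
      else if (target == "I_CaL") clICaL = parse_clamp(cl);
      else if (target == "I_NCX") clINCX = parse_clamp(cl);
      else stop("unknown clamp target: %s", target.c_str());
    }
  }

  const double *p = REAL(params);
  double fss_vstar = 0.0, fss_min = 0.0;
  if (p[pFSSFLAT] > 0.5)
    fss_find_min(p[pFSSVH], p[pFSSSL], &fss_vstar, &fss_min);
  std::vector<double> s(state0.begin(), state0.end());
  std::vector<double> ds(NSTATE);
  Snapshot sn;

  long nstep = (long)std::llround(t_end / dt);
  long nrec = nstep / stride + 2;
  NumericMatrix out(nrec, NTRACECOL);
  long irec = 0;

  bool diverged = false;
  double t_div = NA_REAL;
  bool had_upstroke = false;
  double last_stim_end = -1e18;
  for (int i = 0; i < stim_starts.size(); ++i)
    last_stim_end = std::max(last_stim_end, stim_starts[i] + stim_dur);

  const double wsub_j = VJXN / (VJXN + VSL), wsub_sl = VSL / (VJXN + VSL);

  long step = 0;
  double t = 0.0;
  bool stopped_early = false;

  auto record = [&](double tt) {
    bool cc = clCa.active(tt), cv = clV.active(tt);
    bool cil = clICaL.active(tt), cin = clINCX.active(tt);
    double Isti = 0.0;
    for (int k = 0; k < stim_starts.size(); ++k)
      if (tt >= stim_starts[k] && tt < stim_starts[k] + stim_dur)
        Isti = stim_amp;
    double il_t = NA_REAL, in_t = NA_REAL;
    if (cil || cin) {
      // free evaluation first to know the free current for capture/ramp
      Snapshot fr;
      rhs(s.data(), p, Isti, ds.data(), &fr, cc, cv, false, 0.0, false, 0.0,
          fss_vstar, fss_min);
      if (cil) il_t = clICaL.level(tt, fr.ICaL_j + fr.ICaL_sl);
      if (cin) in_t = clINCX.level(tt, fr.INCX_j + fr.INCX_sl);
    }
    rhs(s.data(), p, Isti, ds.data(), &sn, cc, cv, cil, il_t, cin, in_t,
        fss_vstar, fss_min);
    out(irec, cT) = tt;
    out(irec, cV) = s[iV];
    out(irec, cCASUB) = wsub_j * s[iCAJ] + wsub_sl * s[iCASL];
    out(irec, cCAJ) = s[iCAJ];
    out(irec, cCASL) = s[iCASL];
    out(irec, cCAI) = s[iCAI];
    out(irec, cCAJSR) = s[iCAJSR];
    out(irec, cCANSR) = s[iCANSR];
    out(irec, cICAL) = sn.ICaL_j + sn.ICaL_sl;
    out(irec, cINCX) = sn.INCX_j + sn.INCX_sl;
    out(irec, cIKS) = sn.IKs_j + sn.IKs_sl;
    out(irec, cISTI) = Isti;
    out(irec, cRYRO) = s[iRYR_O];
    ++irec;
  };

  record(0.0);

  for (step = 0; step < nstep; ++step) {
    t = step * dt;

    double Isti = 0.0;
    for (int k = 0; k < stim_starts.size(); ++k)
      if (t >= stim_starts[k] && t < stim_starts[k] + stim_dur)
        Isti = stim_amp;

    bool cc = clCa.active(t), cv = clV.active(t);
    bool cil = clICaL.active(t), cin = clINCX.active(t);

    // state-variable clamps: impose the level before evaluating the RHS
    if (cc) {
      double lv = clCa.level(t, wsub_j * s[iCAJ] + wsub_sl * s[iCASL]);
      if (lv < 1e-7) lv = 1e-7;  // keep concentrations positive
      s[iCAJ] = lv; s[iCASL] = lv;
    }
    if (cv) s[iV] = clV.level(t, s[iV]);

    double il_t = NA_REAL, in_t = NA_REAL;
    if (cil || cin) {
      Snapshot fr;
      rhs(s.data(), p, Isti, ds.data(), &fr, cc, cv, false, 0.0, false, 0.0,
          fss_vstar, fss_min);
      if (cil) il_t = clICaL.level(t, fr.ICaL_j + fr.ICaL_sl);
      if (cin) in_t = clINCX.level(t, fr.INCX_j + fr.INCX_sl);
    }

    rhs(s.data(), p, Isti, ds.data(), nullptr, cc, cv, cil, il_t, cin, in_t,
        fss_vstar, fss_min);

    for (int k = 0; k < NSTATE; ++k) s[k] += dt * ds[k];

    // guard rails: concentrations must stay positive under Euler overshoot
    for (int k = iCAJ; k <= iCANSR; ++k)
      if (s[k] < 1e-9) s[k] = 1e-9;

    double tnext = (step + 1) * dt;

    if (!R_finite(s[iV]) || fabs(s[iV]) > 500.0) {
      diverged = true; t_div = tnext;
      record(tnext);
      break;
    }

    if ((step + 1) % stride == 0) record(tnext);

    if (s[iV] > 0.0) had_upstroke = true;
    if (stop_at_repol && had_upstroke && tnext > last_stim_end &&
        s[iV] < repol_threshold) {
      bool future_stim = false;
      for (int k = 0; k < stim_starts.size(); ++k)
        if (stim_starts[k] > tnext) future_stim = true;
      if (!future_stim) {
        if ((step + 1) % stride != 0) record(tnext);
        stopped_early = true;
        break;
      }
    }
  }

  if (!diverged && !stopped_early && (nstep % stride) != 0) record(nstep * dt);

  NumericMatrix trace(irec, NTRACECOL);
  for (long r = 0; r < irec; ++r)
    for (int ccol = 0; ccol < NTRACECOL; ++ccol)
      trace(r, ccol) = out(r, ccol);
  colnames(trace) = CharacterVector::create(
      "t_ms", "V_m_mV", "Ca_sub_mM", "Ca_jxn_mM", "Ca_sl_mM", "Ca_i_mM",
      "Ca_jsr_mM", "Ca_nsr_mM", "I_CaL_AF", "I_NCX_AF", "I_Ks_AF",
      "I_sti_AF", "ryr_open");

  NumericVector final_state(s.begin(), s.end());
  return List::create(
      _["trace"] = trace,
      _["final_state"] = final_state,
      _["diverged"] = diverged,
      _["t_diverged"] = t_div,
      _["stopped_early"] = stopped_early);
}

//' @noRd
// [[Rcpp::export(name = ".wg_rhs_cpp")]]
List wg_rhs_cpp(NumericVector state, NumericVector params, double Isti,
                bool clamp_ca, bool clamp_v,
                bool clamp_ical, double ical_value,
                bool clamp_incx, double incx_value) {
  if (params.size() != NPAR) stop("parameter vector has wrong length");
  if (state.size() != NSTATE) stop("state vector has wrong length");
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite state entry at position %d", i + 1);

  std::vector<double> ds(NSTATE);
  Snapshot sn;
  const double *p = REAL(params);
  double fss_vstar = 0.0, fss_min = 0.0;
  if (p[pFSSFLAT] > 0.5)
    fss_find_min(p[pFSSVH], p[pFSSSL], &fss_vstar, &fss_min);
  rhs(REAL(state), p, Isti, ds.data(), &sn,
      clamp_ca, clamp_v, clamp_ical, ical_value, clamp_incx, incx_value,
      fss_vstar, fss_min);

  NumericVector deriv(ds.begin(), ds.end());
  NumericVector cur = NumericVector::create(
      _["I_Na"] = sn.INa, _["I_Nab"] = sn.INab,
      _["I_CaL_JXN"] = sn.ICaL_j, _["I_CaL_SL"] = sn.ICaL_sl,
      _["I_Cab_JXN"] = sn.ICab_j, _["I_Cab_SL"] = sn.ICab_sl,
      _["I_pCa_JXN"] = sn.IpCa_j, _["I_pCa_SL"] = sn.IpCa_sl,
      _["I_to"] = sn.Ito, _["I_Kr"] = sn.IKr,
      _["I_Ks_JXN"] = sn.IKs_j, _["I_Ks_SL"] = sn.IKs_sl,
      _["I_K1"] = sn.IK1, _["I_NaK"] = sn.INaK,
      _["I_NCX_JXN"] = sn.INCX_j, _["I_NCX_SL"] = sn.INCX_sl);
  NumericVector gate = NumericVector::create(
      _["d_ss"] = sn.dss, _["tau_d"] = sn.taud,
      _["f_ss"] = sn.fss, _["tau_f"] = sn.tauf,
      _["f_Ca_JXN"] = sn.fca_j, _["f_Ca_SL"] = sn.fca_sl);
  NumericVector flux = NumericVector::create(
      _["J_rel"] = sn.Jrel, _["J_up"] = sn.Jup,
      _["J_tr"] = sn.Jtr, _["J_leak"] = sn.Jleak);
  return List::create(
      _["deriv"] = deriv,
      _["currents"] = cur,
      _["I_ion"] = sn.Iion,
      _["I_sti"] = sn.Isti,
      _["gating"] = gate,
      _["sr_fluxes"] = flux);
}

//' @noRd
// [[Rcpp::export(name = ".wg_fss_cpp")]]
NumericVector wg_fss_cpp(NumericVector v, bool flattened, double vh,
                         double sl) {
  NumericVector out(v.size());
  double vstar = 0.0, fmin = 0.0;
  if (flattened) fss_find_min(vh, sl, &vstar, &fmin);
  for (int i = 0; i < v.size(); ++i)
    out[i] = flattened ? ((v[i] <= vstar) ? fss_raw(v[i], vh, sl) : fmin)
                       : fss_raw(v[i], vh, sl);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".wg_geometry_cpp")]]
NumericVector wg_geometry_cpp() {
  return NumericVector::create(
      _["V_cell_l"] = VCELL, _["V_myo_l"] = VMYO, _["V_sr_l"] = VSR,
      _["V_jsr_l"] = VJSR, _["V_nsr_l"] = VNSR, _["V_sl_l"] = VSL,
      _["V_jxn_l"] = VJXN, _["C_mem_F"] = CMEM);
}

//' @noRd
// [[Rcpp::export(name = ".wg_ca_mass_cpp")]]
double wg_ca_mass_cpp(NumericVector state) {
  // total Ca (free + rapid-equilibrium buffered) in mmol, all compartments
  if (state.size() != NSTATE) stop("state vector has wrong length");
  double Caj = state[iCAJ], Casl = state[iCASL], Cai = state[iCAI];
  double Cajsr = state[iCAJSR], Cansr = state[iCANSR];
  auto bound2 = [](double Ca, double B1, double K1c, double B2, double K2c) {
    return B1 * Ca / (K1c + Ca) + B2 * Ca / (K2c + Ca);
  };
  double mj = VJXN * (Caj + bound2(Caj, BSLL_J, KSLL, BSLH_J, KSLH));
  double msl = VSL * (Casl + bound2(Casl, BSLL_S, KSLL, BSLH_S, KSLH));
  double mi = VMYO * (Cai + BTNC * Cai / (KTNC + Cai) +
                      BCAM * Cai / (KCAM + Cai) + BSRB * Cai / (KSRB + Cai));
  double mjsr = VJSR * (Cajsr + BCSQN * Cajsr / (KCSQN + Cajsr));
  double mnsr = VNSR * Cansr;
  return mj + msl + mi + mjsr + mnsr;
}
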