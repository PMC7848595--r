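/* ToR-ORd human ventricular cardiomyocyte model (Tomek et al. 2019 eLife),
 * endo/epi/mid, with optional bidirectional coupling to the Land 2017
 * contraction model via dynamic Ca-troponin C buffering.
 *
 * State order (NS_TORORD = 43):
 *  0 v    1 nai  2 nass  3 ki   4 kss  5 cai  6 cass  7 cansr 8 cajsr
 *  9 m   10 h   11 j    12 hp  13 jp  14 mL  15 hL   16 hLp
 * 17 a   18 iF  19 iS   20 ap  21 iFp 22 iSp
 * 23 d   24 ff  25 fs   26 fcaf 27 fcas 28 jca 29 ffp 30 fcafp
 * 31 nca_ss 32 nca_i
 * 33 ikr_c0 34 ikr_c1 35 ikr_c2 36 ikr_o 37 ikr_i
 * 38 xs1 39 xs2 40 Jrel_np 41 Jrel_p 42 CaMKt
 * [43..48 Land states when coupled] [last: qca influx accumulator]
 */
#include "emcell.h"

void torord_rhs(double t, const double *y, double *dy, double *out,
                const double *p)
{
    const int celltype = (int) p[P_CELLTYPE];
    const int coupled  = p[P_COUPLED] != 0.0;

    const double v = y[0];
    const double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    const double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    const double m = y[9], h = y[10], jg = y[11], hp = y[12], jp = y[13];
    const double mL = y[14], hL = y[15], hLp = y[16];
    const double a = y[17], iF = y[18], iS = y[19];
    const double ap = y[20], iFp = y[21], iSp = y[22];
    const double d = y[23], ff = y[24], fs = y[25];
    const double fcaf = y[26], fcas = y[27], jca = y[28];
    const double ffp = y[29], fcafp = y[30];
    const double nca_ss = y[31], nca_i = y[32];
    const double c0 = y[33], c1 = y[34], c2 = y[35], o = y[36], ikr_i = y[37];
    const double xs1 = y[38], xs2 = y[39];
    const double Jrelnp = y[40], Jrelp = y[41], CaMKt = y[42];

    const double nao = p[P_NAO], cao = p[P_CAO], ko = p[P_KO];
    const double clo = p[P_CLO], cli = p[P_CLI];
    const double istim = p[P_ISTIM];

    /* cell geometry (cm, uF, uL) */
    const double L = 0.01, rad = 0.0011;
    const double vcell = 1000.0 * 3.14 * rad * rad * L;
    const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    const double Acap = 2.0 * Ageo;
    const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
    const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    const double frt = F_CONST / (R_CONST * T_CONST);
    const double vfrt = v * frt;

    /* CaMKII */
    const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    const double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + CaMKt;
    dy[42] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
    double fp = 1.0 / (1.0 + KmCaMK / CaMKa); /* phosphorylated fraction */

    /* reversal potentials */
    double ENa = (1.0 / frt) * log(nao / nai);
    double EK  = (1.0 / frt) * log(ko / ki);
    const double PKNa = 0.01833;
    double EKs = (1.0 / frt) * log((ko + PKNa * nao) / (ki + PKNa * nai));
    double ECl = (1.0 / frt) * log(cli / clo);

    /* INa (Grandi-type transcription used by ToR-ORd) */
    double mss = 1.0 / pow(1.0 + exp(-(v + 56.86) / 9.03), 2.0);
    double tm = 0.1292 * exp(-pow((v + 45.79) / 15.54, 2.0)) +
                0.06487 * exp(-pow((v - 4.823) / 51.12, 2.0));
    dy[9] = (mss - m) / tm;

    double ah = (v >= -40.0) ? 0.0 : 0.057 * exp(-(v + 80.0) / 6.8);
    double bh = (v >= -40.0)
                ? 0.77 / (0.13 * (1.0 + exp(-(v + 10.66) / 11.1)))
                : 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v);
    double th = 1.0 / (ah + bh);
    double hss = 1.0 / pow(1.0 + exp((v + 71.55) / 7.43), 2.0);
    dy[10] = (hss - h) / th;

    double aj = (v >= -40.0) ? 0.0
        : (-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
          (v + 37.78) / (1.0 + exp(0.311 * (v + 79.23)));
    double bj = (v >= -40.0)
        ? 0.6 * exp(0.057 * v) / (1.0 + exp(-0.1 * (v + 32.0)))
        : 0.02424 * exp(-0.01052 * v) / (1.0 + exp(-0.1378 * (v + 40.14)));
    double tj = 1.0 / (aj + bj);
    double jss = hss;
    dy[11] = (jss - jg) / tj;

    double hssp = 1.0 / pow(1.0 + exp((v + 77.55) / 7.43), 2.0);
    dy[12] = (hssp - hp) / th;
    dy[13] = (jss - jp) / (1.46 * tj);

    double INa = p[P_GNA] * (v - ENa) * m * m * m *
                 ((1.0 - fp) * h * jg + fp * hp * jp);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    dy[14] = (mLss - mL) / tm;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    const double thL = 200.0;
    dy[15] = (hLss - hL) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    dy[16] = (hLssp - hLp) / (3.0 * thL);
    double INaL = p[P_GNAL] * (v - ENa) * mL * ((1.0 - fp) * hL + fp * hLp);

    /* Ito */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    dy[17] = (ass - a) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double delta_epi = (celltype == 1)
        ? 1.0 - 0.95 / (1.0 + exp((v + 70.0) / 5.0)) : 1.0;
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    tiF *= delta_epi; tiS *= delta_epi;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    dy[18] = (iss - iF) / tiF;
    dy[19] = (iss - iS) / tiS;
    double i_to = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    dy[20] = (assp - ap) / ta;
    double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                           exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    dy[21] = (iss - iFp) / (dti_develop * dti_recover * tiF);
    dy[22] = (iss - iSp) / (dti_develop * dti_recover * tiS);
    double ip = AiF * iFp + AiS * iSp;
    double Ito = p[P_GTO] * (v - EK) * ((1.0 - fp) * a * i_to + fp * ap * ip);

    /* ICaL gating */
    double dss = fmin(1.0, 1.0763 * exp(-1.0070 * exp(-0.0829 * v)));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    dy[23] = (dss - d) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    const double Aff = 0.6, Afs = 0.4;
    dy[24] = (fss - ff) / tff;
    dy[25] = (fss - fs) / tfs;
    double f = Aff * ff + Afs * fs;
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    dy[26] = (fcass - fcaf) / tfcaf;
    dy[27] = (fcass - fcas) / tfcas;
    double fca = Afcaf * fcaf + Afcas * fcas;
    double jcass = 1.0 / (1.0 + exp((v + 18.08) / 2.7916));
    dy[28] = (jcass - jca) / 72.5;
    dy[29] = (fss - ffp) / (2.5 * tff);
    double fpg = Aff * ffp + Afs * fs;
    dy[30] = (fcass - fcafp) / (2.5 * tfcaf);
    double fcap = Afcaf * fcafp + Afcas * fcas;

    const double Kmn = 0.002, k2n = 500.0;
    double km2n = jca * 1.0;
    double anca_ss = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    dy[31] = anca_ss * k2n - nca_ss * km2n;
    double anca_i = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cai, 4.0));
    dy[32] = anca_i * k2n - nca_i * km2n;

    /* ionic-activity driving forces (Davies equation) */
    const double dielConstant = 74.0;
    double constA = 1.82e6 * pow(dielConstant * T_CONST, -1.5);
    double Io = 0.5 * (nao + ko + clo + 4.0 * cao) / 1000.0;
    double gden_o = sqrt(Io) / (1.0 + sqrt(Io)) - 0.3 * Io;
    double g_cao = exp(-constA * 4.0 * gden_o);
    double g_nao = exp(-constA * 1.0 * gden_o);
    double g_ko  = g_nao;

    double Iss = 0.5 * (nass + kss + cli + 4.0 * cass) / 1000.0;
    double gden_ss = sqrt(Iss) / (1.0 + sqrt(Iss)) - 0.3 * Iss;
    double g_cass = exp(-constA * 4.0 * gden_ss);
    double g_nass = exp(-constA * 1.0 * gden_ss);
    double g_kss  = g_nass;

    double Ici = 0.5 * (nai + ki + cli + 4.0 * cai) / 1000.0;
    double gden_i = sqrt(Ici) / (1.0 + sqrt(Ici)) - 0.3 * Ici;
    double g_cai = exp(-constA * 4.0 * gden_i);
    double g_nai = exp(-constA * 1.0 * gden_i);
    double g_ki  = g_nai;

    double PhiCaL_ss  = emcell_ghk(2.0, vfrt, g_cass, cass, g_cao, cao);
    double PhiCaNa_ss = emcell_ghk(1.0, vfrt, g_nass, nass, g_nao, nao);
    double PhiCaK_ss  = emcell_ghk(1.0, vfrt, g_kss, kss, g_ko, ko);
    double PhiCaL_i   = emcell_ghk(2.0, vfrt, g_cai, cai, g_cao, cao);
    double PhiCaNa_i  = emcell_ghk(1.0, vfrt, g_nai, nai, g_nao, nao);
    double PhiCaK_i   = emcell_ghk(1.0, vfrt, g_ki, ki, g_ko, ko);

    double PCa = p[P_PCA];
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    const double fSS = 0.8; /* fraction of ICaL in the subspace */

    double gate_np_ss = d * (f * (1.0 - nca_ss) + jca * fca * nca_ss);
    double gate_p_ss  = d * (fpg * (1.0 - nca_ss) + jca * fcap * nca_ss);
    double gate_np_i  = d * (f * (1.0 - nca_i) + jca * fca * nca_i);
    double gate_p_i   = d * (fpg * (1.0 - nca_i) + jca * fcap * nca_i);

    double ICaL_ss = fSS * PhiCaL_ss * ((1.0 - fp) * PCa * gate_np_ss + fp * PCap * gate_p_ss);
    double ICaNa_ss = fSS * PhiCaNa_ss * ((1.0 - fp) * PCaNa * gate_np_ss + fp * PCaNap * gate_p_ss);
    double ICaK_ss = fSS * PhiCaK_ss * ((1.0 - fp) * PCaK * gate_np_ss + fp * PCaKp * gate_p_ss);
    double ICaL_i = (1.0 - fSS) * PhiCaL_i * ((1.0 - fp) * PCa * gate_np_i + fp * PCap * gate_p_i);
    double ICaNa_i = (1.0 - fSS) * PhiCaNa_i * ((1.0 - fp) * PCaNa * gate_np_i + fp * PCaNap * gate_p_i);
    double ICaK_i = (1.0 - fSS) * PhiCaK_i * ((1.0 - fp) * PCaK * gate_np_i + fp * PCaKp * gate_p_i);

    /* IKr: 5-state Markov (closed C0-C1-C2, open O, inactivated I) */
    double alpha = 0.1161 * exp(0.2990 * vfrt);
    double beta  = 0.2442 * exp(-1.604 * vfrt);
    double alpha1 = 1.25 * 0.1235;
    double beta1  = 0.1911;
    double alpha2 = 0.0578 * exp(0.9710 * vfrt);
    double beta2  = 0.349e-3 * exp(-1.062 * vfrt);
    double alphai = 0.2533 * exp(0.5953 * vfrt);
    double betai  = 1.25 * 0.0522 * exp(-0.8209 * vfrt);
    double alphac2ToI = 0.52e-4 * exp(1.525 * vfrt);
    double betaItoC2  = (beta2 * betai * alphac2ToI) / (alpha2 * alphai);
    dy[33] = c1 * beta - c0 * alpha;
    dy[34] = c0 * alpha + c2 * beta1 - c1 * (beta + alpha1);
    dy[35] = c1 * alpha1 + o * beta2 + ikr_i * betaItoC2 -
             c2 * (beta1 + alpha2 + alphac2ToI);
    dy[36] = c2 * alpha2 + ikr_i * betai - o * (beta2 + alphai);
    dy[37] = c2 * alphac2ToI + o * alphai - ikr_i * (betaItoC2 + betai);
    double IKr = p[P_GKR] * sqrt(ko / 5.0) * o * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    dy[38] = (xs1ss - xs1) / txs1;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    dy[39] = (xs1ss - xs2) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double IKs = p[P_GKS] * KsCa * xs1 * xs2 * (v - EKs);

    /* IK1 (instantaneous rectification) */
    double aK1 = 4.094 / (1.0 + exp(0.1217 * (v - EK - 49.934)));
    double bK1 = (15.72 * exp(0.0674 * (v - EK - 3.257)) +
                  exp(0.0618 * (v - EK - 594.31))) /
                 (1.0 + exp(-0.1629 * (v - EK + 14.207)));
    double K1ss = aK1 / (aK1 + bK1);
    double IK1 = p[P_GK1] * sqrt(ko / 5.0) * K1ss * (v - EK);

    /* INaCa (myoplasmic and subspace) */
    const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    const double kcaon = 1.5e6, kcaoff = 5.0e3;
    const double qna = 0.5224, qca = 0.1670;
    const double KmCaAct = 150.0e-6, zca = 2.0, zna = 1.0;
    double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
    double INaCa_i, INaCa_ss;
    {
        double h1 = 1.0 + nai / kna3 * (1.0 + hna);
        double h2 = (nai * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
        double h5 = nai * nai / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff;
        double k6 = h6 * cai * kcaon;
        double k7 = h5 * h2 * wna;
        double k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + pow(KmCaAct / cai, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_i = 0.65 * p[P_GNCX] * allo * (zna * JncxNa + zca * JncxCa);
    }
    {
        double h1 = 1.0 + nass / kna3 * (1.0 + hna);
        double h2 = (nass * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
        double h5 = nass * nass / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff;
        double k6 = h6 * cass * kcaon;
        double k7 = h5 * h2 * wna;
        double k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + pow(KmCaAct / cass, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_ss = 0.35 * p[P_GNCX] * allo * (zna * JncxNa + zca * JncxCa);
    }

    /* INaK */
    double INaK;
    {
        const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
        const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.155;
        const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
        const double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2;
        const double Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
        double Knai = Knai0 * exp(delta * vfrt / 3.0);
        double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
        double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
        double a1 = (k1p * pow(nai / Knai, 3.0)) /
                    (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double b1 = k1m * MgADP;
        double a2 = k2p;
        double b2 = (k2m * pow(nao / Knao, 3.0)) /
                    (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double a3 = (k3p * pow(ko / Kko, 2.0)) /
                    (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
        double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
        double b4 = (k4m * pow(ki / Kki, 2.0)) /
                    (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
        double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
        double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
        double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double zk = 1.0;
        double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        INaK = p[P_PNAK] * (zna * JnakNa + zk * JnakK);
    }

    /* minor currents */
    double xkb = 1.0 / (1.0 + exp(-(v - 10.8968) / 23.9871));
    double IKb = p[P_GKB] * xkb * (v - EK);
    double INab = p[P_PNAB] * emcell_ghk(1.0, vfrt, 1.0, nai, 1.0, nao);
    double ICab = p[P_PCAB] * emcell_ghk(2.0, vfrt, g_cai, cai, g_cao, cao);
    double IpCa = p[P_GPCA] * cai / (0.0005 + cai);

    /* chloride currents (Ca-activated sensed in the subspace) */
    const double KdClCa = 0.1;
    double IClCa = p[P_GCLCA] / (1.0 + KdClCa / cass) * (v - ECl);
    double IClb = p[P_GCLB] * (v - ECl);

    /* diffusion fluxes */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK  = (kss - ki) / 2.0;
    double Jdiff   = (cass - cai) / 0.2;

    /* SR release */
    const double bt = 4.75, cajsr_half = 1.7;
    double a_rel = 0.5 * bt;
    double Jrel_inf = a_rel * (-ICaL_ss) / (1.0 + pow(cajsr_half / cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    dy[40] = (Jrel_inf - Jrelnp) / tau_rel;
    double btp = 1.25 * bt;
    double a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL_ss) / (1.0 + pow(cajsr_half / cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    dy[41] = (Jrel_infp - Jrelp) / tau_relp;
    double Jrel = p[P_JRELB] * ((1.0 - fp) * Jrelnp + fp * Jrelp);

    /* SERCA uptake */
    double upScale = p[P_UPSCALE];
    double Jupnp = upScale * 0.005425 * cai / (cai + 0.00092);
    double Jupp = upScale * 2.75 * 0.005425 * cai / (cai + 0.00092 - 0.00017);
    double Jleak = 0.0048825 * cansr / 15.0;
    double Jup = p[P_JUPB] * ((1.0 - fp) * Jupnp + fp * Jupp - Jleak);
    double Jtr = (cansr - cajsr) / 60.0;

    /* coupled Land contraction */
    double Ta = 0.0, Jtrpn = 0.0;
    if (coupled) {
        double dmech[NS_MECH];
        land_rhs_c(y + NS_TORORD, cai * 1000.0, p, dmech, &Ta);
        for (int k = 0; k < NS_MECH; k++) dy[NS_TORORD + k] = dmech[k];
        Jtrpn = p[P_TRPNMAX] * dmech[2]; /* mM/ms */
    }

    double ICaL_tot = ICaL_ss + ICaL_i;
    double ICaNa_tot = ICaNa_ss + ICaNa_i;
    double ICaK_tot = ICaK_ss + ICaK_i;

    dy[0] = -(INa + INaL + Ito + ICaL_tot + ICaNa_tot + ICaK_tot + IKr + IKs +
              IK1 + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab +
              IClCa + IClb + istim);

    dy[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab + ICaNa_i) *
            Acap / (F_CONST * vmyo) + JdiffNa * vss / vmyo;
    dy[2] = -(ICaNa_ss + 3.0 * INaCa_ss) * Acap / (F_CONST * vss) - JdiffNa;
    dy[3] = -(Ito + IKr + IKs + IK1 + IKb + istim - 2.0 * INaK + ICaK_i) *
            Acap / (F_CONST * vmyo) + JdiffK * vss / vmyo;
    dy[4] = -ICaK_ss * Acap / (F_CONST * vss) - JdiffK;

    const double kmcmdn = 0.00238, kmtrpn = 0.0005;
    const double BSRmax = 0.047, KmBSR = 0.00087;
    const double BSLmax = 1.124, KmBSL = 0.0087;
    const double csqnmax = 10.0, kmcsqn = 0.8;
    double cmdnmax = p[P_CMDNMAX], trpnmax = p[P_TRPNMAX];

    double Bcai;
    if (coupled) {
        Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0));
        dy[5] = Bcai * (-(ICaL_i + IpCa + ICab - 2.0 * INaCa_i) * Acap /
                        (2.0 * F_CONST * vmyo) - Jup * vnsr / vmyo +
                        Jdiff * vss / vmyo - Jtrpn);
    } else {
        Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                      trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
        dy[5] = Bcai * (-(ICaL_i + IpCa + ICab - 2.0 * INaCa_i) * Acap /
                        (2.0 * F_CONST * vmyo) - Jup * vnsr / vmyo +
                        Jdiff * vss / vmyo);
    }
    double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                          BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
    dy[6] = Bcass * (-(ICaL_ss - 2.0 * INaCa_ss) * Acap / (2.0 * F_CONST * vss) +
                     Jrel * vjsr / vss - Jdiff);
    dy[7] = Jup - Jtr * vjsr / vnsr;
    double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
    dy[8] = Bcajsr * (Jtr - Jrel);

    /* auxiliary: integrated net sarcolemmal Ca influx (mM of vmyo) */
    int qidx = NS_TORORD + (coupled ? NS_MECH : 0);
    dy[qidx] = -(ICaL_tot + IpCa + ICab - 2.0 * (INaCa_i + INaCa_ss)) * Acap /
               (2.0 * F_CONST * vmyo);

    if (out) {
        out[O_INA] = INa; out[O_INAL] = INaL; out[O_ITO] = Ito;
        out[O_ICAL] = ICaL_tot; out[O_ICANA] = ICaNa_tot; out[O_ICAK] = ICaK_tot;
        out[O_IKR] = IKr; out[O_IKS] = IKs; out[O_IK1] = IK1;
        out[O_INACA_I] = INaCa_i; out[O_INACA_SS] = INaCa_ss; out[O_INAK] = INaK;
        out[O_IKB] = IKb; out[O_INAB] = INab; out[O_ICAB] = ICab;
        out[O_IPCA] = IpCa; out[O_ICLCA] = IClCa; out[O_ICLB] = IClb;
        out[O_ISTIM] = istim; out[O_JREL] = Jrel; out[O_JUP] = Jup;
        out[O_JDIFF] = Jdiff; out[O_TA] = Ta; out[O_JTRPN] = Jtrpn;
    }
}
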