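/* ORd human ventricular model (O'Hara et al. 2011) with the Dutta et al.
 * 2017 conductance recalibration (applied on the R side), endo/epi/mid,
 * with optional coupling to the Land 2017 contraction model.
 *
 * State order (NS_ORD = 41):
 *  0 v    1 nai  2 nass  3 ki   4 kss  5 cai  6 cass  7 cansr 8 cajsr
 *  9 m   10 hf  11 hs   12 j   13 hsp 14 jp  15 mL  16 hL  17 hLp
 * 18 a   19 iF  20 iS   21 ap  22 iFp 23 iSp
 * 24 d   25 ff  26 fs   27 fcaf 28 fcas 29 jca 30 nca 31 ffp 32 fcafp
 * 33 xrf 34 xrs 35 xs1  36 xs2 37 xk1 38 Jrel_np 39 Jrel_p 40 CaMKt
 * [41..46 Land states when coupled] [last: qca influx accumulator]
 */
#include "emcell.h"

void ord_rhs(double t, const double *y, double *dy, double *out,
             const double *p)
{
    const int celltype = (int) p[P_CELLTYPE];
    const int coupled  = p[P_COUPLED] != 0.0;

    const double v = y[0];
    const double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    const double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    const double m = y[9], hf = y[10], hs = y[11], jg = y[12];
    const double hsp = y[13], jp = y[14];
    const double mL = y[15], hL = y[16], hLp = y[17];
    const double a = y[18], iF = y[19], iS = y[20];
    const double ap = y[21], iFp = y[22], iSp = y[23];
    const double d = y[24], ff = y[25], fs = y[26];
    const double fcaf = y[27], fcas = y[28], jca = y[29], nca = y[30];
    const double ffp = y[31], fcafp = y[32];
    const double xrf = y[33], xrs = y[34], xs1 = y[35], xs2 = y[36];
    const double xk1 = y[37];
    const double Jrelnp = y[38], Jrelp = y[39], CaMKt = y[40];

    const double nao = p[P_NAO], cao = p[P_CAO], ko = p[P_KO];
    const double istim = p[P_ISTIM];

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
    dy[40] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
    double fphos = 1.0 / (1.0 + KmCaMK / CaMKa);

    double ENa = (1.0 / frt) * log(nao / nai);
    double EK  = (1.0 / frt) * log(ko / ki);
    const double PKNa = 0.01833;
    double EKs = (1.0 / frt) * log((ko + PKNa * nao) / (ki + PKNa * nai));

    /* INa (fast) */
    double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    dy[9] = (mss - m) / tm;
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    const double Ahf = 0.99, Ahs = 0.01;
    dy[10] = (hss - hf) / thf;
    dy[11] = (hss - hs) / ths;
    double h = Ahf * hf + Ahs * hs;
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    dy[12] = (jss - jg) / tj;
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    dy[13] = (hssp - hsp) / (3.0 * ths);
    double hp = Ahf * hf + Ahs * hsp;
    dy[14] = (jss - jp) / (1.46 * tj);
    double INa = p[P_GNA] * (v - ENa) * m * m * m *
                 ((1.0 - fphos) * h * jg + fphos * hp * jp);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    dy[15] = (mLss - mL) / tm;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    const double thL = 200.0;
    dy[16] = (hLss - hL) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    dy[17] = (hLssp - hLp) / (3.0 * thL);
    double INaL = p[P_GNAL] * (v - ENa) * mL * ((1.0 - fphos) * hL + fphos * hLp);

    /* Ito */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    dy[18] = (ass - a) / ta;
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
    dy[19] = (iss - iF) / tiF;
    dy[20] = (iss - iS) / tiS;
    double i_to = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    dy[21] = (assp - ap) / ta;
    double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                           exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    dy[22] = (iss - iFp) / (dti_develop * dti_recover * tiF);
    dy[23] = (iss - iSp) / (dti_develop * dti_recover * tiS);
    double ip = AiF * iFp + AiS * iSp;
    double Ito = p[P_GTO] * (v - EK) * ((1.0 - fphos) * a * i_to + fphos * ap * ip);

    /* ICaL (all in subspace) */
    double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    dy[24] = (dss - d) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    const double Aff = 0.6, Afs = 0.4;
    dy[25] = (fss - ff) / tff;
    dy[26] = (fss - fs) / tfs;
    double f = Aff * ff + Afs * fs;
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    dy[27] = (fcass - fcaf) / tfcaf;
    dy[28] = (fcass - fcas) / tfcas;
    double fca = Afcaf * fcaf + Afcas * fcas;
    dy[29] = (fcass - jca) / 75.0;
    dy[31] = (fss - ffp) / (2.5 * tff);
    double fpg = Aff * ffp + Afs * fs;
    dy[32] = (fcass - fcafp) / (2.5 * tfcaf);
    double fcap = Afcaf * fcafp + Afcas * fcas;
    const double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double anca = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    dy[30] = anca * k2n - nca * km2n;

    double PhiCaL  = emcell_ghk(2.0, vfrt, 1.0, cass, 0.341, cao);
    double PhiCaNa = emcell_ghk(1.0, vfrt, 0.75, nass, 0.75, nao);
    double PhiCaK  = emcell_ghk(1.0, vfrt, 0.75, kss, 0.75, ko);
    double PCa = p[P_PCA];
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
    double gate_p  = d * (fpg * (1.0 - nca) + jca * fcap * nca);
    double ICaL = PhiCaL * ((1.0 - fphos) * PCa * gate_np + fphos * PCap * gate_p);
    double ICaNa = PhiCaNa * ((1.0 - fphos) * PCaNa * gate_np + fphos * PCaNap * gate_p);
    double ICaK = PhiCaK * ((1.0 - fphos) * PCaK * gate_np + fphos * PCaKp * gate_p);

    /* IKr (two-component HH gate) */
    double xrss = 1.0 / (1.0 + exp(-(v + 8.337) / 6.789));
    double txrf = 12.98 + 1.0 / (0.3652 * exp((v - 31.66) / 3.869) +
                                 4.123e-5 * exp(-(v - 47.78) / 20.38));
    double txrs = 1.865 + 1.0 / (0.06629 * exp((v - 34.70) / 7.355) +
                                 1.128e-5 * exp(-(v - 29.74) / 25.94));
    double Axrf = 1.0 / (1.0 + exp((v + 54.81) / 38.21));
    double Axrs = 1.0 - Axrf;
    dy[33] = (xrss - xrf) / txrf;
    dy[34] = (xrss - xrs) / txrs;
    double xr = Axrf * xrf + Axrs * xrs;
    double rkr = 1.0 / ((1.0 + exp((v + 55.0) / 75.0)) *
                        (1.0 + exp((v - 10.0) / 30.0)));
    double IKr = p[P_GKR] * sqrt(ko / 5.4) * xr * rkr * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    dy[35] = (xs1ss - xs1) / txs1;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    dy[36] = (xs1ss - xs2) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double IKs = p[P_GKS] * KsCa * xs1 * xs2 * (v - EKs);

    /* IK1 (gated) */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33));
    dy[37] = (xk1ss - xk1) / txk1;
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    double IK1 = p[P_GK1] * sqrt(ko) * rk1 * xk1 * (v - EK);

    /* INaCa */
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
        INaCa_i = 0.8 * p[P_GNCX] * allo * (zna * JncxNa + zca * JncxCa);
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
        INaCa_ss = 0.2 * p[P_GNCX] * allo * (zna * JncxNa + zca * JncxCa);
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
    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    double IKb = p[P_GKB] * xkb * (v - EK);
    double INab = p[P_PNAB] * emcell_ghk(1.0, vfrt, 1.0, nai, 1.0, nao);
    double ICab = p[P_PCAB] * emcell_ghk(2.0, vfrt, 1.0, cai, 0.341, cao);
    double IpCa = p[P_GPCA] * cai / (0.0005 + cai);

    /* diffusion fluxes */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK  = (kss - ki) / 2.0;
    double Jdiff   = (cass - cai) / 0.2;

    /* SR release */
    const double bt = 4.75;
    double a_rel = 0.5 * bt;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    dy[38] = (Jrel_inf - Jrelnp) / tau_rel;
    double btp = 1.25 * bt;
    double a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    dy[39] = (Jrel_infp - Jrelp) / tau_relp;
    double Jrel = p[P_JRELB] * ((1.0 - fphos) * Jrelnp + fphos * Jrelp);

    /* SERCA uptake */
    double upScale = p[P_UPSCALE];
    double Jupnp = upScale * 0.004375 * cai / (cai + 0.00092);
    double Jupp = upScale * 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = p[P_JUPB] * ((1.0 - fphos) * Jupnp + fphos * Jupp - Jleak);
    double Jtr = (cansr - cajsr) / 100.0;

    /* coupled Land contraction */
    double Ta = 0.0, Jtrpn = 0.0;
    if (coupled) {
        double dmech[NS_MECH];
        land_rhs_c(y + NS_ORD, cai * 1000.0, p, dmech, &Ta);
        for (int k = 0; k < NS_MECH; k++) dy[NS_ORD + k] = dmech[k];
        Jtrpn = p[P_TRPNMAX] * dmech[2];
    }

    dy[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
              INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + istim);

    dy[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
            (F_CONST * vmyo) + JdiffNa * vss / vmyo;
    dy[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (F_CONST * vss) - JdiffNa;
    dy[3] = -(Ito + IKr + IKs + IK1 + IKb + istim - 2.0 * INaK) * Acap /
            (F_CONST * vmyo) + JdiffK * vss / vmyo;
    dy[4] = -ICaK * Acap / (F_CONST * vss) - JdiffK;

    const double kmcmdn = 0.00238, kmtrpn = 0.0005;
    const double BSRmax = 0.047, KmBSR = 0.00087;
    const double BSLmax = 1.124, KmBSL = 0.0087;
    const double csqnmax = 10.0, kmcsqn = 0.8;
    double cmdnmax = p[P_CMDNMAX], trpnmax = p[P_TRPNMAX];

    double Bcai;
    if (coupled) {
        Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0));
        dy[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                        (2.0 * F_CONST * vmyo) - Jup * vnsr / vmyo +
                        Jdiff * vss / vmyo - Jtrpn);
    } else {
        Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                      trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
        dy[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                        (2.0 * F_CONST * vmyo) - Jup * vnsr / vmyo +
                        Jdiff * vss / vmyo);
    }
    double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                          BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
    dy[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * F_CONST * vss) +
                     Jrel * vjsr / vss - Jdiff);
    dy[7] = Jup - Jtr * vjsr / vnsr;
    double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
    dy[8] = Bcajsr * (Jtr - Jrel);

    int qidx = NS_ORD + (coupled ? NS_MECH : 0);
    dy[qidx] = -(ICaL + IpCa + ICab - 2.0 * (INaCa_i + INaCa_ss)) * Acap /
               (2.0 * F_CONST * vmyo);

    if (out) {
        out[O_INA] = INa; out[O_INAL] = INaL; out[O_ITO] = Ito;
        out[O_ICAL] = ICaL; out[O_ICANA] = ICaNa; out[O_ICAK] = ICaK;
        out[O_IKR] = IKr; out[O_IKS] = IKs; out[O_IK1] = IK1;
        out[O_INACA_I] = INaCa_i; out[O_INACA_SS] = INaCa_ss; out[O_INAK] = INaK;
        out[O_IKB] = IKb; out[O_INAB] = INab; out[O_ICAB] = ICab;
        out[O_IPCA] = IpCa; out[O_ICLCA] = 0.0; out[O_ICLB] = 0.0;
        out[O_ISTIM] = istim; out[O_JREL] = Jrel; out[O_JUP] = Jup;
        out[O_JDIFF] = Jdiff; out[O_TA] = Ta; out[O_JTRPN] = Jtrpn;
    }
}
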