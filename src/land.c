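/* Land 2017 human active contraction model: troponin C and tropomyosin
 * kinetics plus a three-state crossbridge scheme (unattached U, weakly bound
 * W, strongly bound S) with distortion variables zeta_s/zeta_w.
 *
 * State order: XS, XW, CaTRPN, TmBlocked, ZETAS, ZETAW.
 * cai is supplied in uM; rates are per ms; tension in kPa (= mN/mm^2).
 */
#include "emcell.h"

void land_rhs_c(const double *m, double cai_uM, const double *p, double *dm,
                double *Ta)
{
    double XS       = fmax(0.0, m[0]);
    double XW       = fmax(0.0, m[1]);
    double CaTRPN   = fmax(0.0, m[2]);
    double TmBlocked = m[3];
    double ZETAS    = m[4];
    double ZETAW    = m[5];

    double perm50 = p[P_PERM50], ntrpn = p[P_NTRPN], koff = p[P_KTRPN];
    double dr = p[P_DR], wfrac = p[P_WFRAC], TOT_A = p[P_TOTA];
    double ktm_unblock = p[P_KTM], nperm = p[P_NTM];
    double beta0 = p[P_BETA0], beta1 = p[P_BETA1];
    double gamma_s = p[P_GAMMAS], gamma_wu = p[P_GAMMAW], phi = p[P_PHI];
    double ca50 = p[P_CA50], Tref = p[P_TREF];
    double k_uw = p[P_KUW], k_ws = p[P_KWS];
    double lambda = p[P_LAMBDA], dlambda = p[P_DLAMBDA];

    double lam12  = fmin(lambda, 1.2);
    double lam087 = fmin(lam12, 0.87);
    double hlam   = fmax(0.0, 1.0 + beta0 * (lam12 + lam087 - 1.87));

    /* derived crossbridge rates from duty ratios */
    double k_wu = k_uw * (1.0 / wfrac - 1.0) - k_ws;
    double k_su = k_ws * (1.0 / dr - 1.0) * wfrac;
    double cdw  = phi * k_uw * (1.0 - dr) * (1.0 - wfrac) / ((1.0 - dr) * wfrac);
    double cds  = phi * k_ws * (1.0 - dr) * wfrac / dr;
    double A    = (0.25 * TOT_A) / ((1.0 - dr) * wfrac + dr) * (dr / 0.25);

    double XU = (1.0 - TmBlocked) - XW - XS;

    double xb_ws = k_ws * XW;
    double xb_uw = k_uw * XU;
    double xb_wu = k_wu * XW;
    double xb_su = k_su * XS;

    double zs_pos = (ZETAS > 0.0) ? ZETAS : 0.0;
    double zs_neg = (ZETAS < -1.0) ? (-ZETAS - 1.0) : 0.0;
    double gamma_rate_s = gamma_s * fmax(zs_pos, zs_neg);
    double gamma_rate_w = gamma_wu * fabs(ZETAW);

    dm[0] = xb_ws - xb_su - gamma_rate_s * XS;
    dm[1] = xb_uw - xb_wu - xb_ws - gamma_rate_w * XW;

    /* troponin C: length-dependent Ca50 (additive form, uM) */
    double ca50l = ca50 + beta1 * (lam12 - 1.0);
    double cai_s = fmax(cai_uM, 0.0);
    dm[2] = koff * (pow(cai_s / ca50l, ntrpn) * (1.0 - CaTRPN) - CaTRPN);

    /* tropomyosin: blocked <-> permissive, CaTRPN-cooperative */
    double XSSS = dr * 0.5;
    double XWSS = (1.0 - dr) * wfrac * 0.5;
    double ktm_block = ktm_unblock * pow(perm50, nperm) * 0.5 /
                       (0.5 - XSSS - XWSS);
    double ctrpn = fmax(CaTRPN, 1e-12);
    dm[3] = ktm_block * fmin(100.0, pow(ctrpn, -nperm / 2.0)) * XU -
            ktm_unblock * pow(ctrpn, nperm / 2.0) * TmBlocked;

    dm[4] = A * dlambda - cds * ZETAS;
    dm[5] = A * dlambda - cdw * ZETAW;

    *Ta = hlam * (Tref / dr) * ((ZETAS + 1.0) * XS + ZETAW * XW);
}
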