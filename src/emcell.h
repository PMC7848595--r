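#ifndef EMCELL_H
#define EMCELL_H

#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* Parameter vector layout. Must match .p_layout in R/params.R. All
   conductances arrive fully resolved: base value x celltype scaling x
   channel_scale (drug block). */
#define P_VARIANT    0   /* 1 = ToR-ORd, 2 = ORd (Dutta-modified) */
#define P_CELLTYPE   1   /* 0 endo, 1 epi, 2 mid */
#define P_COUPLED    2   /* 0 = EP-only (steady-state troponin buffer), 1 = Land-coupled */
#define P_ISTIM      3   /* uA/uF, negative while the pulse is on */
#define P_LAMBDA     4   /* extension ratio */
#define P_DLAMBDA    5   /* 1/ms */
#define P_GNA        6
#define P_GNAL       7
#define P_GTO        8
#define P_PCA        9
#define P_GKR       10
#define P_GKS       11
#define P_GK1       12
#define P_GNCX      13
#define P_PNAK      14
#define P_GKB       15
#define P_PNAB      16
#define P_PCAB      17
#define P_GPCA      18
#define P_GCLCA     19
#define P_GCLB      20
#define P_JRELB     21  /* release flux scale (mid x1.7 folded in) */
#define P_JUPB      22
#define P_UPSCALE   23  /* SERCA celltype scale */
#define P_CMDNMAX   24  /* mM, celltype-resolved */
#define P_TRPNMAX   25  /* mM */
#define P_NAO       26
#define P_CAO       27
#define P_KO        28
#define P_CLO       29
#define P_CLI       30
/* Land 2017 parameters */
#define P_CA50      31  /* uM */
#define P_NTRPN     32
#define P_KTRPN     33  /* 1/ms */
#define P_NTM       34  /* tropomyosin cooperativity exponent */
#define P_KTM       35  /* 1/ms, tropomyosin unblocking rate */
#define P_TREF      36  /* kPa */
#define P_KUW       37  /* 1/ms */
#define P_KWS       38  /* 1/ms */
#define P_PERM50    39
#define P_DR        40
#define P_WFRAC     41
#define P_TOTA      42
#define P_GAMMAS    43
#define P_GAMMAW    44
#define P_PHI       45
#define P_BETA0     46
#define P_BETA1     47
#define N_PARMS     48

#define NS_TORORD 43
#define NS_ORD    41
#define NS_MECH    6
/* each system carries one trailing auxiliary state: integrated net
   sarcolemmal Ca influx expressed as mM of myoplasmic volume */

#define N_OUT 24
enum { O_INA = 0, O_INAL, O_ITO, O_ICAL, O_ICANA, O_ICAK, O_IKR, O_IKS, O_IK1,
       O_INACA_I, O_INACA_SS, O_INAK, O_IKB, O_INAB, O_ICAB, O_IPCA,
       O_ICLCA, O_ICLB, O_ISTIM, O_JREL, O_JUP, O_JDIFF, O_TA, O_JTRPN };

#define F_CONST 96485.0
#define R_CONST 8314.0
#define T_CONST 310.0

void torord_rhs(double t, const double *y, double *dy, double *out, const double *p);
void ord_rhs(double t, const double *y, double *dy, double *out, const double *p);
void land_rhs_c(const double *m, double cai_uM, const double *p, double *dm,
                double *Ta);

/* GHK-type flux per unit permeability:
 * z^2*vffrt*(gi*ci*exp(z*vfrt)-go*co)/(exp(z*vfrt)-1), with the removable
 * singularity at v = 0 handled by its limit. */
static R_INLINE double emcell_ghk(double z, double vfrt, double gi, double ci,
                                  double go, double co)
{
    double a = z * vfrt;
    if (fabs(a) < 1e-7)
        return z * F_CONST * (gi * ci * (1.0 + 0.5 * a) - go * co * (1.0 - 0.5 * a));
    return z * F_CONST * a * (gi * ci * exp(a) - go * co) / (exp(a) - 1.0);
}

#endif
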