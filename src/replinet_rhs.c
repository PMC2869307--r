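/* Mean-field balance equations for the origin-activation network.
 *
 * State vector (0-based):
 *   0..9    S0..S9     origin-state fractions, unphosphorylated-ORC layer
 *   10..19  S0P..S9P   mirrored layer with S-Cdk-phosphorylated ORC
 *   20 Cdc6  21 Cdt1  22 Mcm  23 Cdt1.Mcm  24 Cdc45  25 GINS  26 Pol
 *   27 GINS.Pol  28 Dpb11
 *   29..37  Sld2 with j = 0..8 random sites phosphorylated
 *   38      pSld2 (Thr84-phosphorylated, active)
 *   39..47  Sld3 with j = 0..8 sites phosphorylated (active form = 39 + nSld3)
 *   48 Dpb11.pSld2  49 Dpb11.pSld3  50 11-3-2  51 free active S-Cdk
 *   52..60  Sic1(j).S-Cdk complexes   61..69 free Sic1(j)
 *   70..73  sinks: degraded Cdc6, exported Cdt1, exported Mcm, degraded Sic1
 *   74..76  replisome-sequestered Mcm / Cdc45 / GINS.Pol (relicensing channel)
 *   77 cumulative firing flux (per origin)   78 cumulative relicensing flux
 *
 * Origin states are fractions; free species are molar.  Fluxes between the
 * two representations are scaled by Cori, the molar concentration equivalent
 * of the full origin complement.
 */
#include <R.h>
#include <math.h>

#define NSTATE 81
#define NPARMS 62

static double p[NPARMS];

void replinet_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }

/* Michaelis-Menten rate of a kinase/phosphatase acting on substrate
 * concentration s with enzyme concentration e. */
static double mm(double kcat, double km, double e, double s)
{
    return kcat * e * s / (km + s);
}

void replinet_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double Cori   = p[0];
    const double g1Amp  = p[1], g1Mid = p[2], g1Hill = p[3];
    const int orcLayer  = (int) p[4];
    const int clamp     = (int) p[5];
    const int constSld2 = (int) p[6], constSld3 = (int) p[7];
    const int ns  = (int) p[8];   /* Sic1 random sites  */
    const int n2  = (int) p[9];   /* Sld2 random sites (Thr84 extra) */
    const int n3  = (int) p[10];  /* Sld3 sites */
    const int variant = (int) p[11];
    const double Pt   = p[12], Ddk = p[13];
    const double kon6 = p[14], koff6 = p[15], konCM = p[16], koffCM = p[17];
    const double konL = p[18], koffL = p[19], kload = p[20], Kav = p[21];
    const double kd6 = p[22], kexp = p[23];
    const double kcatSic = p[24], KmSic = p[25], kpSic = p[26];
    const double kdegSic = p[27], konSC = p[28], koffSC = p[29];
    const double kcatMcm = p[30], KmMcm = p[31];
    const double kon45 = p[32], koff45 = p[33];
    const double konT = p[34], koffT = p[35];
    const double konGPo = p[36], koffGPo = p[37];
    const double krel = p[38], kfire = p[39];
    const double kcatOrc = p[40], KmOrc = p[41], k16 = p[42];
    const double kcat2 = p[43], Km2 = p[44], kcatT84 = p[45], KmT84 = p[46];
    const double kcat3 = p[47], Km3 = p[48], kcatP = p[49], KmP = p[50];
    const double konD2 = p[51], koffD2 = p[52], konD3 = p[53], koffD3 = p[54];
    const double konT2 = p[55], koffT2 = p[56], konT3 = p[57], koffT3 = p[58];
    const double konGP0 = p[59], koffGP0 = p[60];
    const double scdkTot = p[61];

    int i, j, b, L;
    double v, vf, vb;

    if (*neq < NSTATE) error("state vector too short");
    for (i = 0; i < NSTATE; i++) ydot[i] = 0.0;
    if (yout && ip && ip[0] >= 1) yout[0] = 0.0;

    /* G1-Cdk input: Hill-in-time sigmoid, zero at t = 0 */
    double g1 = 0.0, g1n = 0.0;
    if (*t > 0.0) {
        double th = pow(*t, g1Hill), mh = pow(g1Mid, g1Hill);
        g1n = th / (th + mh);
        g1  = g1Amp * g1n;
    }

    const double C6   = pos(y[20]), Ct1 = pos(y[21]), Mcm = pos(y[22]);
    const double CM   = pos(y[23]), C45 = pos(y[24]);
    const double GINS = pos(y[25]), Pol = pos(y[26]), GP = pos(y[27]);
    const double Dpb  = pos(y[28]);
    const double p2   = pos(y[38]);                 /* active pSld2  */
    const double p3   = pos(y[39 + n3]);            /* active pSld3  */
    const double D2   = pos(y[48]), D3 = pos(y[49]), T = pos(y[50]);
    const double SCdk = pos(y[51]);
    const double scdkn = scdkTot > 0.0 ? fmin(SCdk / scdkTot, 1.0) : 0.0;

    /* ---- origin-state chains, both ORC layers ---- */
    for (L = 0; L < 2; L++) {
        b = 10 * L;
        /* S0 + Cdc6 <-> S1 */
        vf = kon6 * C6 * pos(y[b + 0]);
        vb = koff6 * pos(y[b + 1]);
        ydot[b + 0] += vb - vf;  ydot[b + 1] += vf - vb;
        ydot[20]    += Cori * (vb - vf);
        if (L == 0) {
            /* S1 + Cdt1.Mcm <-> S2 (blocked in the P layer)  */
            vf = konL * CM * pos(y[1]);
            vb = koffL * pos(y[2]);
            ydot[1] += vb - vf;  ydot[2] += vf - vb;
            ydot[23] += Cori * (vb - vf);
            /* S2 -> S3: Mcm loaded, Cdc6 and Cdt1 released */
            v = kload * pos(y[2]);
            ydot[2] -= v;  ydot[3] += v;
            ydot[20] += Cori * v;  ydot[21] += Cori * v;
        }
        /* S3 -> S4: Mcm phosphorylation, S-Cdk + Ddk driven, processive */
        v = kcatMcm * (SCdk + Ddk) * pos(y[b + 3]) /
            (KmMcm + Cori * pos(y[b + 3]));
        ydot[b + 3] -= v;  ydot[b + 4] += v;
        /* S4 + Cdc45 <-> S5 */
        vf = kon45 * C45 * pos(y[b + 4]);
        vb = koff45 * pos(y[b + 5]);
        ydot[b + 4] += vb - vf;  ydot[b + 5] += vf - vb;
        ydot[24]    += Cori * (vb - vf);
        if (!variant) {
            /* S5 + 11-3-2 <-> S6 (activator pre-assembled in solution) */
            vf = konT * T * pos(y[b + 5]);
            vb = koffT * pos(y[b + 6]);
            ydot[b + 5] += vb - vf;  ydot[b + 6] += vf - vb;
            ydot[50]    += Cori * (vb - vf);
            /* S6 + GINS.Pol <-> S7 */
            vf = konGPo * GP * pos(y[b + 6]);
            vb = koffGPo * pos(y[b + 7]);
            ydot[b + 6] += vb - vf;  ydot[b + 7] += vf - vb;
            ydot[27]    += Cori * (vb - vf);
        } else {
            /* binding-order variant: Dpb11.pSld3 docks first ... */
            vf = konT * D3 * pos(y[b + 5]);
            vb = koffT * pos(y[b + 6]);
            ydot[b + 5] += vb - vf;  ydot[b + 6] += vf - vb;
            ydot[49]    += Cori * (vb - vf);
            /* ... pSld2 joins with GINS.Pol recruitment (irreversible) */
            double kd2 = konD2 > 0.0 ? koffD2 / konD2 : 1e-6;
            vf = konGPo * GP * pos(y[b + 6]) * (p2 / (p2 + kd2));
            ydot[b + 6] -= vf;  ydot[b + 7] += vf;
            ydot[27] -= Cori * vf;  ydot[38] -= Cori * vf;
        }
        /* S7 -> S8: 11-3-2 released intact */
        v = krel * pos(y[b + 7]);
        ydot[b + 7] -= v;  ydot[b + 8] += v;
        ydot[50] += Cori * v;
        /* S8 -> S9: firing */
        v = kfire * pos(y[b + 8]);
        ydot[b + 8] -= v;  ydot[b + 9] += v;
        ydot[77] += v;                       /* firing accumulator */
        ydot[79] += v * (*t);                /* exact moment integrals */
        ydot[80] += v * (*t) * (*t);
        if (yout && ip && ip[0] >= 1) yout[0] += v;
    }

    /* relicensing channel (unphosphorylated layer only), gated by k16 */
    if (k16 > 0.0) {
        v = k16 * pos(y[9]) * (C6 / (C6 + Kav)) * (CM / (CM + Kav));
        ydot[9] -= v;  ydot[3] += v;
        ydot[23] -= Cori * v;  ydot[21] += Cori * v;   /* new Mcm loaded */
        ydot[74] += Cori * v;  ydot[75] += Cori * v;  ydot[76] += Cori * v;
        ydot[78] += v;
    }

    /* ORC phosphorylation by free S-Cdk: only origins without an engaged
     * pre-RC/pre-IC expose ORC - the licensing states S0/S1 (inhibiting
     * licensing) and the fired state S9 (inhibiting relicensing).  S2 is
     * shielded by bound Cdt1. */
    if (orcLayer) {
        static const int orcTargets[3] = {0, 1, 9};
        for (j = 0; j < 3; j++) {
            i = orcTargets[j];
            v = kcatOrc * SCdk * pos(y[i]) / (KmOrc + Cori * pos(y[i]));
            ydot[i] -= v;  ydot[10 + i] += v;
        }
    }

    /* ---- free-protein reactions ---- */
    /* Cdt1 + Mcm <-> Cdt1.Mcm */
    vf = konCM * Ct1 * Mcm;  vb = koffCM * CM;
    ydot[21] += vb - vf;  ydot[22] += vb - vf;  ydot[23] += vf - vb;
    /* GINS + Pol <-> GINS.Pol */
    vf = konGP0 * GINS * Pol;  vb = koffGP0 * GP;
    ydot[25] += vb - vf;  ydot[26] += vb - vf;  ydot[27] += vf - vb;
    /* G1-Cdk-dependent degradation of free Cdc6 */
    v = kd6 * g1n * C6;
    ydot[20] -= v;  ydot[70] += v;
    /* Cdk-dependent nuclear export of free Cdt1 and free Mcm */
    v = kexp * (g1n + scdkn) * Ct1;
    ydot[21] -= v;  ydot[71] += v;
    v = kexp * (g1n + scdkn) * Mcm;
    ydot[22] -= v;  ydot[72] += v;

    /* Sld2: random-sequential distributive chain + hierarchical Thr84 */
    if (!constSld2) {
        for (j = 0; j < n2; j++) {
            vf = (n2 - j) * mm(kcat2, Km2, SCdk, pos(y[29 + j]));
            ydot[29 + j] -= vf;  ydot[30 + j] += vf;
        }
        for (j = 1; j <= n2; j++) {
            vb = j * mm(kcatP, KmP, Pt, pos(y[29 + j]));
            ydot[29 + j] -= vb;  ydot[28 + j] += vb;
        }
        v = mm(kcatT84, KmT84, SCdk, pos(y[29 + n2]));
        ydot[29 + n2] -= v;  ydot[38] += v;
        v = mm(kcatP, KmP, Pt, p2);
        ydot[38] -= v;  ydot[29 + n2] += v;
    }
    /* Sld3: random distributive chain, no hierarchical site */
    if (!constSld3) {
        for (j = 0; j < n3; j++) {
            vf = (n3 - j) * mm(kcat3, Km3, SCdk, pos(y[39 + j]));
            ydot[39 + j] -= vf;  ydot[40 + j] += vf;
        }
        for (j = 1; j <= n3; j++) {
            vb = j * mm(kcatP, KmP, Pt, pos(y[39 + j]));
            ydot[39 + j] -= vb;  ydot[38 + j] += vb;
        }
    }
    /* 11-3-2 assembly in solution (both routes) */
    vf = konD2 * Dpb * p2;  vb = koffD2 * D2;
    ydot[28] += vb - vf;  ydot[38] += vb - vf;  ydot[48] += vf - vb;
    vf = konD3 * Dpb * p3;  vb = koffD3 * D3;
    ydot[28] += vb - vf;  ydot[39 + n3] += vb - vf;  ydot[49] += vf - vb;
    vf = konT2 * D2 * p3;  vb = koffT2 * T;
    ydot[48] += vb - vf;  ydot[39 + n3] += vb - vf;  ydot[50] += vf - vb;
    vf = konT3 * D3 * p2;  vb = koffT3 * T;
    ydot[49] += vb - vf;  ydot[38] += vb - vf;  ydot[50] += vf - vb;

    /* Sic1 chains: G1-Cdk phosphorylation, phosphatase, degradation,
     * binding of free Sic1 to free S-Cdk (phospho-state preserved) */
    for (j = 0; j < ns; j++) {
        vf = (ns - j) * mm(kcatSic, KmSic, g1, pos(y[52 + j]));
        ydot[52 + j] -= vf;  ydot[53 + j] += vf;
        vf = (ns - j) * mm(kcatSic, KmSic, g1, pos(y[61 + j]));
        ydot[61 + j] -= vf;  ydot[62 + j] += vf;
    }
    for (j = 1; j <= ns; j++) {
        vb = j * kpSic * Pt * pos(y[52 + j]);
        ydot[52 + j] -= vb;  ydot[51 + j] += vb;
        vb = j * kpSic * Pt * pos(y[61 + j]);
        ydot[61 + j] -= vb;  ydot[60 + j] += vb;
    }
    v = kdegSic * pos(y[52 + ns]);          /* complexed: releases S-Cdk */
    ydot[52 + ns] -= v;  ydot[51] += v;  ydot[73] += v;
    v = kdegSic * pos(y[61 + ns]);
    ydot[61 + ns] -= v;  ydot[73] += v;
    for (j = 0; j <= ns; j++) {
        vf = konSC * pos(y[61 + j]) * SCdk;
        vb = koffSC * pos(y[52 + j]);
        ydot[61 + j] += vb - vf;  ydot[51] += vb - vf;  ydot[52 + j] += vf - vb;
    }

    /* clamped-pool mode: freeze every free species and sink */
    if (clamp) for (i = 20; i <= 76; i++) ydot[i] = 0.0;

    if (yout && ip && ip[0] >= 2) yout[1] = g1;
}
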