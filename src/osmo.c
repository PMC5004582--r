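/* Compiled right-hand sides and fixed-step integrators for the
 * osmoregulation model and the generic closed loop.
 *
 * The osmoshock model state is (V, uHOG, Gly, Glye, z, Q) where
 *   V    cell volume (fraction of initial volume)
 *   uHOG Hog1 activation
 *   Gly  intracellular glycerol amount
 *   Glye extracellular glycerol amount
 *   z    cumulative integral of uHOG (drives the integral Hog branches)
 *   Q    cumulative integral of vHOG (diagnostic; glycerol bookkeeping)
 *
 * The parameter vector layout below is produced by .osmo_parms_vector()
 * on the R side and must stay in sync with it.
 *
 * Step inputs (shock / disturbance) are evaluated at the *start* of each
 * fixed step and held across the Runge-Kutta stages, so that a step whose
 * onset falls on a grid point is integrated exactly piecewise (stage
 * times touching the onset do not leak the post-jump value into the
 * pre-jump step).
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define N_OSMO_PARMS 22

#define P_KP1   pr[0]
#define P_S     pr[1]
#define P_VB    pr[2]
#define P_V0    pr[3]
#define P_PT0   pr[4]
#define P_PEEQ  pr[5]
#define P_VPT0  pr[6]
#define P_VE    pr[7]
#define P_BHOG  pr[8]
#define P_AHOG  pr[9]
#define P_KFPS1 pr[10]
#define P_BFPS1 pr[11]
#define P_KKFPS pr[12]
#define P_NFPS1 pr[13]
#define P_HKIND pr[14]   /* 1 = Hill (incl. proportional), 2 = ideal integral,
                            3 = finite-window integral (fixed-step only) */
#define P_KHOG  pr[15]
#define P_BHHOG pr[16]
#define P_KKHOG pr[17]
#define P_NHOG  pr[18]
#define P_TM    pr[19]
#define P_AMP   pr[20]   /* shock amplitude, osmotic pressure units */
#define P_TON   pr[21]

static double osmo_parms[N_OSMO_PARMS];

/* Core model right-hand side.  zlag = z(t - Tm) for the finite-window
 * integral Hog branch (ignored otherwise).  noise_f / noise_h are additive
 * perturbations on the two controller outputs (zero for deterministic use).
 * out[] receives (uFps1, vHOG, uDiff, e, Pt, Pi, Pe). */
static void osmo_core(const double *pr, double t, const double *y,
                      double *ydot, double *out, double zlag,
                      double noise_f, double noise_h)
{
    double V = y[0], uH = y[1];
    double Gly = y[2] > 0 ? y[2] : 0;     /* guard transient overdraw */
    double Glye = y[3] > 0 ? y[3] : 0;
    double z = y[4];

    double Pe = P_PEEQ + (t >= P_TON ? P_AMP : 0);
    double Pt = V > P_VPT0 ? P_PT0 * (V - P_VPT0) / (P_V0 - P_VPT0) : 0;
    double Pi = (P_S + Gly) / (V - P_VB);
    double e = P_PT0 - Pt;

    double ae = fabs(e), uF, vH, uD;
    double hill = R_pow(ae, P_NFPS1);
    uF = P_KFPS1 - (e > 0 ? 1 : (e < 0 ? -1 : 0)) * P_KFPS1 * hill /
         (P_BFPS1 * hill + P_KKFPS);
    if (uF < 0) uF = 0;
    uF += noise_f;

    int hk = (int) P_HKIND;
    if (hk == 1) {
        if (uH > 0) {
            double uh = R_pow(uH, P_NHOG);
            vH = P_KHOG * uh / (P_BHHOG * uh + P_KKHOG);
        } else vH = 0;
    } else if (hk == 2) {
        vH = P_KHOG * z;
    } else {
        vH = P_KHOG * (z - zlag);
    }
    vH += noise_h;

    uD = uF * (Gly / (V - P_VB) - Glye / P_VE);

    ydot[0] = P_KP1 * (Pi - Pe - Pt);
    ydot[1] = P_BHOG * e - P_AHOG * uH;
    ydot[2] = vH - uD;
    ydot[3] = uD;
    ydot[4] = uH;
    ydot[5] = vH;

    if (out) {
        out[0] = uF; out[1] = vH; out[2] = uD; out[3] = e;
        out[4] = Pt; out[5] = Pi; out[6] = Pe;
    }
}

/* ---- deSolve interface (adaptive solvers; Hill / ideal-integral only) ---- */

void osmo_initmod(void (*odeparms)(int *, double *))
{
    int n = N_OSMO_PARMS;
    odeparms(&n, osmo_parms);
}

void osmo_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    if (ip[0] < 7) error("nout must be >= 7");
    osmo_core(osmo_parms, *t, y, ydot, yout, 0.0, 0.0, 0.0);
}

/* ---- fixed-step RK4 with optional controller-output noise ----
 * Keeps the full z history so the finite-window integral branch can look
 * up z(t - Tm) (held constant across the stages of one step).  Noise is
 * drawn once per step, scaled by 1/sqrt(h), and held across stages, so the
 * integrated perturbation over one step has sd sigma * sqrt(h). */
SEXP C_osmo_fixed(SEXP s_parms, SEXP s_y0, SEXP s_h, SEXP s_nstep,
                  SEXP s_report_every, SEXP s_sigma)
{
    const double *pr = REAL(s_parms);
    double h = asReal(s_h);
    int nstep = asInteger(s_nstep), rep = asInteger(s_report_every);
    double sig_f = REAL(s_sigma)[0], sig_h = REAL(s_sigma)[1];
    int noisy = (sig_f > 0 || sig_h > 0);
    double sqh = sqrt(h);

    int nrow = nstep / rep + 1, ncol = 1 + 6 + 7;
    SEXP ans = PROTECT(allocMatrix(REALSXP, nrow, ncol));
    double *m = REAL(ans);

    double y[6], k1[6], k2[6], k3[6], k4[6], yt[6], out[7];
    double *zhist = (double *) R_alloc((size_t) nstep + 1, sizeof(double));
    for (int i = 0; i < 6; i++) y[i] = REAL(s_y0)[i];
    zhist[0] = y[4];

    if (noisy) GetRNGstate();

    int row = 0;
    for (int step = 0; step <= nstep; step++) {
        double t = step * h;
        double zlag = 0;
        if ((int) P_HKIND == 3) {
            double tl = t - P_TM;
            if (tl > 0) {
                double fi = tl / h;
                int i0 = (int) floor(fi);
                if (i0 >= step) i0 = step - 1;
                double w = fi - i0;
                zlag = (1 - w) * zhist[i0] + w * zhist[i0 + 1];
            }
        }

        if (step % rep == 0) {
            /* record outputs at the current state (deterministic view) */
            osmo_core(pr, t, y, k1, out, zlag, 0.0, 0.0);
            m[row] = t;
            for (int i = 0; i < 6; i++) m[row + (size_t) nrow * (1 + i)] = y[i];
            for (int i = 0; i < 7; i++) m[row + (size_t) nrow * (7 + i)] = out[i];
            row++;
        }
        if (step == nstep) break;

        double nf = noisy && sig_f > 0 ? sig_f * norm_rand() / sqh : 0;
        double nh = noisy && sig_h > 0 ? sig_h * norm_rand() / sqh : 0;

        /* t only gates the step input; hold the step-start value */
        osmo_core(pr, t, y, k1, NULL, zlag, nf, nh);
        for (int i = 0; i < 6; i++) yt[i] = y[i] + 0.5 * h * k1[i];
        osmo_core(pr, t, yt, k2, NULL, zlag, nf, nh);
        for (int i = 0; i < 6; i++) yt[i] = y[i] + 0.5 * h * k2[i];
        osmo_core(pr, t, yt, k3, NULL, zlag, nf, nh);
        for (int i = 0; i < 6; i++) yt[i] = y[i] + h * k3[i];
        osmo_core(pr, t, yt, k4, NULL, zlag, nf, nh);
        for (int i = 0; i < 6; i++)
            y[i] += h * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]) / 6;
        if (y[2] < 0) y[2] = 0;   /* glycerol floors */
        if (y[3] < 0) y[3] = 0;
        zhist[step + 1] = y[4];
        if (!R_FINITE(y[0]) || y[0] <= P_VB) {
            if (noisy) PutRNGstate();
            UNPROTECT(1);
            error("state left validity region at t = %g (V = %g)", t + h, y[0]);
        }
    }

    if (noisy) PutRNGstate();
    UNPROTECT(1);
    return ans;
}

/* ---- generic first-order closed loop ----
 * Internal state x with x' = -a x + b (v0 + u); measured output
 * y = x + ud(t); error e = r - y.  v0 is the nominal controller-side
 * bias sustaining the pre-disturbance equilibrium (a*y0/b).  Controller
 * kinds: 1 P, 2 I, 3 FI, 4 UNF, 5 SMC, 6 SAT.  The cumulative error
 * integral E (E' = e) drives the integral laws; its per-step history
 * backs the finite window. */

typedef struct {
    int kind;
    double kp, ki, K, n, m, Tm;
    double a, b, r, v0, a_ud, t_on;
} loop_spec;

static double loop_g(const loop_spec *L, double e, double E, double Elag)
{
    double ae, s;
    switch (L->kind) {
    case 1: return L->kp * e;
    case 2: return L->ki * E;
    case 3: return L->ki * (E - Elag);
    case 4:
        ae = fabs(e);
        if (ae == 0) return 0;
        s = R_pow(ae, L->n);
        return (e > 0 ? 1 : -1) * L->kp * s / (s + R_pow(L->K, L->n));
    case 5: return L->kp * (e > 0 ? 1 : (e < 0 ? -1 : 0));
    default: {
        double me = L->m * e;
        if (me > 1) me = 1; else if (me < -1) me = -1;
        return L->kp * me;
    }
    }
}

static void loop_rhs(const loop_spec *L, double t, double x, double E,
                     double Elag, double *dx, double *dE,
                     double *e_out, double *u_out)
{
    double ud = t >= L->t_on ? L->a_ud : 0;
    double e = L->r - (x + ud);
    double u = loop_g(L, e, E, Elag);
    *dx = -L->a * x + L->b * (L->v0 + u);
    *dE = e;
    if (e_out) { *e_out = e; *u_out = u; }
}

SEXP C_loop_fixed(SEXP s_kind, SEXP s_cpar, SEXP s_lpar, SEXP s_h,
                  SEXP s_nstep, SEXP s_report_every)
{
    loop_spec L;
    const double *cp = REAL(s_cpar), *lp = REAL(s_lpar);
    L.kind = asInteger(s_kind);
    L.kp = cp[0]; L.ki = cp[1]; L.K = cp[2]; L.n = cp[3];
    L.m = cp[4]; L.Tm = cp[5];
    L.a = lp[0]; L.b = lp[1]; L.r = lp[2]; L.v0 = lp[4];
    L.a_ud = lp[5]; L.t_on = lp[6];
    double y0 = lp[3];

    double h = asReal(s_h);
    int nstep = asInteger(s_nstep), rep = asInteger(s_report_every);
    int nrow = nstep / rep + 1;
    SEXP ans = PROTECT(allocMatrix(REALSXP, nrow, 4)); /* t, y, e, u */
    double *m = REAL(ans);

    double *Ehist = (double *) R_alloc((size_t) nstep + 1, sizeof(double));
    double x = y0, E = 0;
    Ehist[0] = 0;

    int row = 0;
    for (int step = 0; step <= nstep; step++) {
        double t = step * h;
        double Elag = 0;
        if (L.kind == 3) {
            double tl = t - L.Tm;
            if (tl > 0) {
                double fi = tl / h;
                int i0 = (int) floor(fi);
                if (i0 >= step) i0 = step - 1;
                double w = fi - i0;
                Elag = (1 - w) * Ehist[i0] + w * Ehist[i0 + 1];
            }
        }

        double dx, dE, e, u;
        if (step % rep == 0) {
            double ud = t >= L.t_on ? L.a_ud : 0;
            e = L.r - (x + ud);
            u = loop_g(&L, e, E, Elag);
            m[row] = t;
            m[row + (size_t) nrow] = x + ud;
            m[row + 2 * (size_t) nrow] = e;
            m[row + 3 * (size_t) nrow] = u;
            row++;
        }
        if (step == nstep) break;

        double k1x, k1E, k2x, k2E, k3x, k3E, k4x, k4E;
        /* t only gates the disturbance; hold the step-start value */
        loop_rhs(&L, t, x, E, Elag, &k1x, &k1E, NULL, NULL);
        loop_rhs(&L, t, x + 0.5 * h * k1x, E + 0.5 * h * k1E,
                 Elag, &k2x, &k2E, NULL, NULL);
        loop_rhs(&L, t, x + 0.5 * h * k2x, E + 0.5 * h * k2E,
                 Elag, &k3x, &k3E, NULL, NULL);
        loop_rhs(&L, t, x + h * k3x, E + h * k3E,
                 Elag, &k4x, &k4E, NULL, NULL);
        x += h * (k1x + 2 * k2x + 2 * k3x + k4x) / 6;
        E += h * (k1E + 2 * k2E + 2 * k3E + k4E) / 6;
        Ehist[step + 1] = E;
        if (!R_FINITE(x)) {
            UNPROTECT(1);
            error("closed-loop state diverged at t = %g", t + h);
        }
    }

    UNPROTECT(1);
    return ans;
}

/* ---- registration ---- */

static const R_CallMethodDef call_entries[] = {
    {"C_osmo_fixed", (DL_FUNC) &C_osmo_fixed, 6},
    {"C_loop_fixed", (DL_FUNC) &C_loop_fixed, 6},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"osmo_initmod", (DL_FUNC) &osmo_initmod, 1},
    {"osmo_derivs",  (DL_FUNC) &osmo_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_osmounf(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
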