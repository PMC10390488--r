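/* Compiled right-hand side for the per-clone tumor growth ODE system.
 *
 * State layout (clone-major): y[5*c + 0..4] = P, Q, D, K, I for clone c.
 *   P  proliferating cells          Q  quiescent cells
 *   D  dead cells (not yet cleared) K  carrying capacity (cells)
 *   I  immune pressure (dimensionless)
 *
 * Parameter vector (fixed length NPARMS, padded from R):
 *   [0]  n_clones (<= MAXCLONES)
 *   [1]  v_cell cm3   [2] d_rim cm    [3] K_max cells
 *   [4]  lambda_prolif /d  [5] k_pq /d  [6] k_qp /d
 *   [7]  delta0 /d  [8] delta_q /d  [9] k_cl /d
 *   [10] kappa_I /d  [11] gamma_drug /d  [12] alpha_ang /d
 *   [13] rho_imm /d  [14] h_imm cells  [15] d_imm /d
 *   PK block (time unit: days):
 *   [16] pk_mode (0 none, 1 infusion-equivalent average, 2 Bateman superposition)
 *   [17] A = F*dose*ka/(Vd*(ka-ke)) mg/L  [18] ka /d  [19] ke /d
 *   [20] tau /d (dosing interval)  [21] t_start d  [22] t_end d
 *   [23] css mg/L (steady-state average, mode 1)
 *   [24] Imax  [25] hill
 *   Per-clone blocks (length MAXCLONES each):
 *   [26+c]  IC50_eff mg/L  [42+c] eff (drug-effect retention on signal)
 *   [58+c]  s0tot = s0*(1 + g_egfr + m_prolif)
 */
#include <R.h>
#include <math.h>

#define MAXCLONES 16
#define NPARMS (26 + 3 * MAXCLONES)

static double parms[NPARMS];

void tumor_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* truncated geometric superposition sum: doses every tau from 0, n doses,
 * evaluated at time t >= (n-1)*tau since first dose */
static double geo_sum(double k, double t, double tau, int n)
{
    double u = t - (n - 1) * tau;
    return (exp(-k * u) - exp(-k * (u + n * tau))) / (1.0 - exp(-k * tau));
}

static double plasma_conc(double t)
{
    int mode = (int) parms[16];
    double A = parms[17], ka = parms[18], ke = parms[19], tau = parms[20];
    double t0 = parms[21], t1 = parms[22], css = parms[23];

    if (mode == 0 || t <= t0)
        return 0.0;
    if (mode == 1) {
        /* zero-order infusion equivalent of repeated dosing */
        if (t <= t1)
            return css * (1.0 - exp(-ke * (t - t0)));
        double cend = css * (1.0 - exp(-ke * (t1 - t0)));
        return cend * exp(-ke * (t - t1));
    }
    /* mode 2: exact Bateman superposition, doses at t0, t0+tau, ... */
    double tr = t - t0;
    int n = (int) floor(tr / tau) + 1;
    if (t1 < t && t1 > t0) {
        int nmax = (int) floor((t1 - t0) / tau) + 1;
        if (n > nmax) n = nmax;
    }
    double c = A * (geo_sum(ke, tr, tau, n) - geo_sum(ka, tr, tau, n));
    return c > 0.0 ? c : 0.0;
}

void tumor_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int nc = (int) parms[0];
    double vc = parms[1], drim = parms[2], Kmax = parms[3];
    double lam = parms[4], kpq = parms[5], kqp = parms[6];
    double d0 = parms[7], dq = parms[8], kcl = parms[9];
    double kI = parms[10], gd = parms[11], aang = parms[12];
    double rimm = parms[13], himm = parms[14], dimm = parms[15];
    double Imax = parms[24], hill = parms[25];

    double C = plasma_conc(*t);
    double Ch = (C > 0.0) ? pow(C, hill) : 0.0;

    double Ntot = 0.0, Vtot = 0.0;
    for (int c = 0; c < nc; c++) {
        double P = fmax(y[5 * c], 0.0), Q = fmax(y[5 * c + 1], 0.0);
        double D = fmax(y[5 * c + 2], 0.0);
        Ntot += P + Q;
        Vtot += P + Q + D;
    }
    Vtot *= vc;
    double r = cbrt(3.0 * Vtot / (4.0 * M_PI));
    double phi = (r <= drim) ? 1.0 : 1.0 - pow((r - drim) / r, 3.0);

    for (int c = 0; c < nc; c++) {
        double P = fmax(y[5 * c], 0.0), Q = fmax(y[5 * c + 1], 0.0);
        double D = fmax(y[5 * c + 2], 0.0), K = y[5 * c + 3];
        double I = fmax(y[5 * c + 4], 0.0);

        double ic = parms[26 + c], eff = parms[42 + c], s0t = parms[58 + c];
        double inh = (Ch > 0.0) ? Imax * Ch / (pow(ic, hill) + Ch) : 0.0;
        double s = s0t * (1.0 - eff * inh);

        double kill_p = d0 + kI * I + gd * eff * inh;
        double kill_q = dq + kI * I;
        double comp = (K > 0.0) ? 1.0 - (P + Q) / K : 0.0;
        double grow = lam * s * phi * comp * P;

        ydot[5 * c]     = grow - kpq * (1.0 - phi) * P + kqp * phi * Q - kill_p * P;
        ydot[5 * c + 1] = kpq * (1.0 - phi) * P - kqp * phi * Q - kill_q * Q;
        ydot[5 * c + 2] = kill_p * P + kill_q * Q - kcl * D;
        ydot[5 * c + 3] = aang * (P + Q) * (1.0 - K / Kmax);
        ydot[5 * c + 4] = rimm * Ntot / (himm + Ntot) - dimm * I;
    }

    if (ip[0] >= 2) {
        yout[0] = Vtot;
        yout[1] = r;
    }
}
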