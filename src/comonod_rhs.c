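/* Compiled right-hand side of the co-culture reactor ODE system for deSolve.
 *
 * State vector: y = (X_1..X_K, M_1..M_nm, [psi pools per species]).
 * The parameter vector (padded to PARMS_LEN on the R side) is laid out as
 *   [0] K  [1] nm  [2] D  [3] dynamic  [4] scaled_by_biomass  [5] (unused)
 *   [6 .. 6+nm-1] feed
 * then, per species:
 *   n, sub[n] (1-based metabolite index), Ks[n], q_max[n], Yx[n], YxQ[n],
 *   K_ind[n], eps_c[n], eps_i[n], delta[n], gain[n],
 *   psi_met[nm*n] (column-major), psi_fixed[n]
 * Mirrors rhs_core() in R/reactor.R exactly; the two are cross-checked in
 * the test suite.
 */
#include <R.h>

#define PARMS_LEN 4096
#define MAX_PW 64

static double p[PARMS_LEN];

void comonod_initmod(void (*odeparms)(int *, double *))
{
    int N = PARMS_LEN;
    odeparms(&N, p);
}

void comonod_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int K = (int) p[0], nm = (int) p[1];
    const double D = p[2];
    const int dynamic = (int) p[3], scaled = (int) p[4];
    const double *feed = p + 6;
    int off_p = 6 + nm;
    int off_psi = K + nm;

    double M[16], dM[16];
    for (int m = 0; m < nm; m++) {
        const double raw = y[K + m];
        M[m] = raw > 0 ? raw : 0;
        dM[m] = D * (feed[m] - raw);
    }

    for (int k = 0; k < K; k++) {
        const int n = (int) p[off_p];
        const double *sub = p + off_p + 1;
        const double *Ks = sub + n, *qmax = Ks + n, *Yx = qmax + n,
                     *YxQ = Yx + n, *Kind = YxQ + n, *epsc = Kind + n,
                     *epsi = epsc + n, *delta = epsi + n, *gain = delta + n,
                     *psimet = gain + n, *psifix = psimet + (long) nm * n;
        const double X = y[k] > 0 ? y[k] : 0;

        double S[MAX_PW], H[MAX_PW], psi[MAX_PW], mu[MAX_PW],
               u[MAX_PW], v[MAX_PW];
        double smu = 0, mmax = 0;
        for (int i = 0; i < n; i++) {
            const int si = (int) sub[i] - 1;
            S[i] = M[si];
            H[i] = S[i] / (Ks[i] + S[i]);
            double ps = dynamic ? y[off_psi + i] : psifix[i];
            psi[i] = ps > 0 ? ps : 0;
            mu[i] = YxQ[i] * psi[i] * H[i];
            smu += mu[i];
            if (mu[i] > mmax) mmax = mu[i];
        }
        for (int i = 0; i < n; i++) {
            if (smu > 1e-12) {
                u[i] = mu[i] / smu;
                v[i] = mu[i] / mmax;
            } else {
                u[i] = 1.0 / n;
                v[i] = 1.0;
            }
        }

        double dX = 0, mutot = 0;
        for (int i = 0; i < n; i++) {
            const double rate = v[i] * qmax[i] * psi[i] * H[i] * X;
            dX += Yx[i] * rate;
            for (int m = 0; m < nm; m++)
                dM[m] += psimet[(long) i * nm + m] * rate;
            mutot += v[i] * mu[i];
        }
        ydot[k] = dX - D * y[k];

        if (dynamic) {
            for (int i = 0; i < n; i++) {
                const double Hind = S[i] / (Kind[i] + S[i]);
                double ind = u[i] * epsi[i] * Hind;
                if (scaled) ind *= X;
                ydot[off_psi + i] =
                    (epsc[i] + ind) * gain[i] - (delta[i] + mutot) * psi[i];
            }
            off_psi += n;
        }
        off_p += 1 + 11 * n + nm * n;
    }
    for (int m = 0; m < nm; m++)
        ydot[K + m] = dM[m];
}
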