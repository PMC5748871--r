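/* Compiled right-hand sides for the dimensionless ring oscillators,
 * in the deSolve compiled-model interface. State y = (x, v), x = u_r/R.
 *
 * parms layout:
 *  [0] law code: 0 Skalak polynomial (any truncation), 1 Hariton,
 *      2 Mooney-Rivlin, 3 linear
 *  [1] p_hat      constant normalized pressure of the current segment
 *  [2] coupled    1: load = (1+x) p_hat, 0: load = load_scale * p_hat
 *  [3] load_scale
 *  [4..7] law parameters:
 *      Skalak: c0, c1, c2, c3 (truncations pass zeros)
 *      Hariton: b, lam_z0, -, -
 *      Mooney-Rivlin: beta, lam_z0, -, -
 *      linear: k_hat, -, -, -
 *  [8] stretch cap on 1+x
 */
#include <R.h>
#include <math.h>

static double parms[9];

void ring_init(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

static double restoring(double x)
{
    const int law = (int) parms[0];
    const double lam = 1.0 + x;
    switch (law) {
    case 0:
        return parms[4] + x * (parms[5] + x * (parms[6] + x * parms[7]));
    case 1: {
        const double b = parms[4], lz = parms[5];
        const double lz2 = lz * lz, lam2 = lam * lam;
        const double I1m3 = lam2 + lz2 + 1.0 / (lam2 * lz2) - 3.0;
        double z = 0.5 * b * I1m3 * I1m3;
        if (z > 700.0) z = 700.0;   /* guarded separately by ring_root */
        return (2.0 / lz) * (lam - 1.0 / (lam2 * lam * lz2)) * I1m3 * exp(z);
    }
    case 2: {
        const double beta = parms[4], lz = parms[5];
        const double lz2 = lz * lz, lam3 = lam * lam * lam;
        return ((0.5 + beta) * (lam - 1.0 / (lam3 * lz2)) +
                (0.5 - beta) * (lam * lz2 - 1.0 / lam3)) / lz;
    }
    default:
        return parms[4] * x;
    }
}

void ring_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double x = y[0];
    const double load = (parms[2] > 0.5) ? (1.0 + x) * parms[1]
                                         : parms[3] * parms[1];
    ydot[0] = y[1];
    ydot[1] = load - restoring(x);
}

/* Stop integration at ring collapse, at the stretch cap, and (Hariton)
 * before the energy exponent overflows. */
void ring_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *rpar, int *ipar)
{
    const double lam = 1.0 + y[0];
    gout[0] = lam - parms[8];
    gout[1] = lam - 1e-10;
    if ((int) parms[0] == 1) {
        const double b = parms[4], lz = parms[5];
        const double lam2 = lam * lam, lz2 = lz * lz;
        const double I1m3 = lam2 + lz2 + 1.0 / (lam2 * lz2) - 3.0;
        gout[2] = 699.0 - 0.5 * b * I1m3 * I1m3;
    } else {
        gout[2] = 1.0;
    }
}
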