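/* Mean-field rate equations of the predator-prey-parasite system, in the
 * form expected by deSolve's compiled-code interface.
 *
 * State order:     (xU, xI, yU, yI, z)
 * Parameter order: (gx, rx, dx, K, S, Qx, nz, dz, fy, ky, Qy, rp, re, dy)
 */
#include <R.h>

static double p[14];

#define gx p[0]
#define rx p[1]
#define dx p[2]
#define K  p[3]
#define S  p[4]
#define Qx p[5]
#define nz p[6]
#define dz p[7]
#define fy p[8]
#define ky p[9]
#define Qy p[10]
#define rp p[11]
#define re p[12]
#define dy p[13]

void tritroph_initmod(void (*odeparms)(int *, double *)) {
    int n = 14;
    odeparms(&n, p);
}

void tritroph_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
    /* clamp tiny negative excursions of the integrator before evaluating */
    double xU = y[0] > 0 ? y[0] : 0;
    double xI = y[1] > 0 ? y[1] : 0;
    double yU = y[2] > 0 ? y[2] : 0;
    double yI = y[3] > 0 ? y[3] : 0;
    double z  = y[4] > 0 ? y[4] : 0;

    ydot[0] = gx * (rx * xI + xU) - (xI + xU) * xU / K - dx * xU
              - Qx * S * xU * z - fy * xU * (yI + yU);
    ydot[1] = -(xI + xU) * xI / K - dx * xI + Qx * S * xU * z
              - fy * xI * (yI + yU);
    ydot[2] = ky * fy * xU * (rp * yI + yU)
              + (re * ky * (1 - Qy) - (1 - rp * ky) * Qy) * fy * xI * yU
              + (rp * re * ky * (1 - Qy) + rp * rp * ky * Qy) * fy * xI * yI
              - dy * yU;
    ydot[3] = -dy * yI + Qy * fy * xI * yU;
    ydot[4] = -Qx * S * xU * z + nz * Qy * fy * xI * (yI + yU) - dz * z;
}
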