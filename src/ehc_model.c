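/* Compiled right-hand side and Jacobian for the enterohepatic circulation
 * model, in the deSolve compiled-model convention.
 *
 * The system is linear time-varying:
 *   dy/dt = A0 y + s + e(t) * (E y) + b(t) * (B y)
 * where e(t) is the meal-triggered gallbladder emptying amplitude and b(t)
 * the gallbladder-refill bypass window, both smooth products of logistic
 * ramps. E moves gallbladder content (states 4:6, 1-based) to the proximal
 * small intestine (7:9); B reroutes the hepatic output of the liver states
 * (1:3) from the gallbladder to the proximal small intestine.
 *
 * Parameter vector layout (passed from R, see .system_parms()):
 *   parms[0]        n (number of states, 37)
 *   parms[1..6]     t_open, t_close, amp, t_refill_end, c_bypass, steep
 *   parms[7..43]    s (length 37)
 *   parms[44..]     A0, column-major, 37*37
 */

#include <math.h>

#define N_STATE 37
#define P_LEN (1 + 6 + N_STATE + N_STATE * N_STATE)

static double parms[P_LEN];

void ehc_init(void (*odeparms)(int *, double *))
{
    int n = P_LEN;
    odeparms(&n, parms);
}

static double logistic(double x)
{
    if (x > 40.0) return 1.0;
    if (x < -40.0) return 0.0;
    return 1.0 / (1.0 + exp(-x));
}

static void windows(double t, double *e, double *b)
{
    double t_open = parms[1], t_close = parms[2], amp = parms[3];
    double t_refill_end = parms[4], steep = parms[6];
    double up = logistic((t - t_open) / steep);
    *e = amp * up * logistic((t_close - t) / steep);
    *b = up * logistic((t_refill_end - t) / steep);
}

void ehc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *s = parms + 7;
    const double *A = parms + 7 + N_STATE;
    double e, b, cb = parms[5];
    int i, j;

    for (i = 0; i < N_STATE; i++) ydot[i] = s[i];
    for (j = 0; j < N_STATE; j++) {
        double yj = y[j];
        if (yj != 0.0) {
            const double *col = A + j * N_STATE;
            for (i = 0; i < N_STATE; i++) ydot[i] += col[i] * yj;
        }
    }
    windows(*t, &e, &b);
    for (j = 0; j < 3; j++) {
        double g = e * y[3 + j];        /* gallbladder -> si_proximal */
        ydot[3 + j] -= g;
        ydot[6 + j] += g;
        double r = b * cb * y[j];       /* liver output rerouted past gb */
        ydot[3 + j] -= r;
        ydot[6 + j] += r;
    }
}

void ehc_jac(int *neq, double *t, double *y, int *ml, int *mu,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    const double *A = parms + 7 + N_STATE;
    double e, b, cb = parms[5];
    int i, j, nr = *nrowpd;

    for (j = 0; j < N_STATE; j++)
        for (i = 0; i < N_STATE; i++)
            pd[i + j * nr] = A[i + j * N_STATE];
    windows(*t, &e, &b);
    for (j = 0; j < 3; j++) {
        pd[(3 + j) + (3 + j) * nr] -= e;
        pd[(6 + j) + (3 + j) * nr] += e;
        pd[(3 + j) + j * nr] -= b * cb;
        pd[(6 + j) + j * nr] += b * cb;
    }
}
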