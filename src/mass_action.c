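/* Mass-action right-hand side of the DNAzyme cleavage network, in the
 * parameter order k_on, k_off, k_clv, k_lig, k_rls, k_bin and the state
 * order S, E, ES, EP, P.  Interface follows deSolve's compiled-model
 * convention (initializer + derivative function looked up by name). */
#include <R.h>

static double parms[6];
#define K_ON  parms[0]
#define K_OFF parms[1]
#define K_CLV parms[2]
#define K_LIG parms[3]
#define K_RLS parms[4]
#define K_BIN parms[5]

void dzkin_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void dzkin_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double S = y[0], E = y[1], ES = y[2], EP = y[3], P = y[4];
    double v_on  = K_ON * S * E;   /* association     E + S  -> ES */
    double v_off = K_OFF * ES;     /* dissociation    ES     -> E + S */
    double v_clv = K_CLV * ES;     /* cleavage        ES     -> EP */
    double v_lig = K_LIG * EP;     /* ligation        EP     -> ES */
    double v_rls = K_RLS * EP;     /* product release EP     -> E + P */
    double v_bin = K_BIN * E * P;  /* product binding E + P  -> EP */

    ydot[0] = -v_on + v_off;                    /* S  */
    ydot[1] = -v_on + v_off + v_rls - v_bin;    /* E  */
    ydot[2] =  v_on - v_off - v_clv + v_lig;    /* ES */
    ydot[3] =  v_clv - v_lig - v_rls + v_bin;   /* EP */
    ydot[4] =  v_rls - v_bin;                   /* P  */
}
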