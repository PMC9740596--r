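/* Compiled right-hand side of the 23-balance whole-body lipid metabolism
 * model, in the deSolve compiled-model convention.  Mirrors the pure-R
 * reference implementation (R/model.R); tests enforce agreement.
 *
 * Parameter vector: the 81 kinetic constants in the order of
 * parameter_info(), followed by 4 forcing entries
 * (sg_amp, sg_scale, sf_amp, sf_scale); bolus mode = zero amplitudes.
 */

#include <R.h>
#include <math.h>

#define NPAR 85
static double parms[NPAR];

/* indices into parms, matching parameter_info() row order */
enum {
  i_alpha_A, i_alpha_L, i_alpha_M, i_beta_6, i_beta_G, i_beta_f, i_beta_L,
  i_beta_M, i_mu_amp, i_mu_b, i_mu_e, i_mu_s, i_mu_1, i_mu_3, i_mu_4,
  i_c_0, i_c_c, i_d_ba, i_k_10, i_k_11, i_k_12, i_k_13, i_k_14, i_k_22,
  i_k_5, i_k_6, i_k_61, i_k_6p, i_k_7, i_k_8, i_k_9, i_k_9a, i_k_a,
  i_k_aa, i_k_ai, i_k_al, i_k_ba, i_k_bl, i_k_bm, i_k_cl, i_k_cm, i_k_d,
  i_k_dl, i_k_dy, i_k_ft, i_k_ga, i_k_gi, i_k_gl, i_k_gl2, i_k_gm,
  i_k_gm2, i_k_gp, i_k_lp, i_k_LG, i_k_LH, i_k_MH, i_k_na, i_k_p, i_k_p6,
  i_k_pp, i_k_r, i_k_rep, i_k_t, i_k_yl, i_k_ym, i_l_max, i_m_max, i_v,
  i_v_10, i_v_12, i_v_6, i_v_8, i_v_9, i_v_LG, i_v_LH, i_v_MH, i_y_0,
  i_alpha_G, i_alpha_F, i_m_s, i_m_e,
  i_sg_amp, i_sg_scale, i_sf_amp, i_sf_scale
};

void lipid_initmod(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, parms);
}

void lipid_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
  const double I = y[0],
    G_L = y[1], P_L = y[2], Y_L = y[3], R_L = y[4], A_L = y[5],
    S_L = y[6], T_L = y[7],
    G_M = y[8], Y_M = y[9], P_M = y[10], R_M = y[11], A_M = y[12],
    T_M = y[13], P = y[14],
    T_A = y[15], A_A = y[16], L_A = y[17], G_A = y[18],
    T_CB = y[19], A_B = y[20], T_LB = y[21], G_B = y[22];

  const double SG = parms[i_sg_amp] > 0.0
    ? parms[i_sg_amp] * exp(-(*t) / parms[i_sg_scale]) : 0.0;
  const double SF = parms[i_sf_amp] > 0.0
    ? parms[i_sf_amp] * exp(-(*t) / parms[i_sf_scale]) : 0.0;

  const double glucokinase = parms[i_v_LG] * G_L / (parms[i_k_LG] + G_L);
  const double hexokinase_L = parms[i_v_LH] * G_L / (parms[i_k_LH] + G_L)
    / (1.0 + parms[i_k_rep] * P_L);
  const double hexokinase_M = parms[i_v_MH] * G_M / (parms[i_k_MH] + G_M)
    / (1.0 + parms[i_k_rep] * P_M);
  const double gsyn_L = 0.5 * parms[i_k_yl] * I * P_L
    * (1.0 + tanh((parms[i_l_max] - Y_L) / parms[i_c_0]));
  const double gly_L_y = parms[i_beta_L] / (1.0 + parms[i_k_dl] * I)
    * Y_L / (Y_L + parms[i_y_0]);
  const double gly_L_p = parms[i_beta_L] / (1.0 + parms[i_k_p6] * I)
    * Y_L / (Y_L + parms[i_y_0]);
  const double gsyn_M = 0.5 * parms[i_k_ym] * I * P_M
    * (1.0 + tanh((parms[i_m_max] - Y_M) / parms[i_c_0]));
  const double gly_M = parms[i_beta_M] / (1.0 + parms[i_k_dy] * I)
    * Y_M / (Y_M + parms[i_y_0]);
  const double dnl = parms[i_beta_6] * R_L / (1.0 + parms[i_k_p6] * I);
  const double v6sec = parms[i_v_6] * A_L / (parms[i_k_6] + A_L);
  const double v8_tl = parms[i_v_8] * A_L / (parms[i_k_8] + A_L);
  const double v8_al = parms[i_v_8] * A_L / (1.0 + parms[i_k_5] * I);
  const double k7ox = parms[i_k_7] * A_L / (1.0 + parms[i_k_5] * I);
  const double tl_rel = parms[i_v_10] * T_L / (parms[i_k_10] + T_L);
  const double F_I = parms[i_k_12] * tanh((parms[i_v_12] - I) / parms[i_k_13])
    + parms[i_k_14];
  const double vldl = F_I * parms[i_v_9] * T_L / (parms[i_k_9] + T_L);
  const double secretion = parms[i_k_11]
    + parms[i_k_22] * erf((G_B - parms[i_v]) / parms[i_c_c]);
  const double glc_MB = (1.0 + parms[i_k_gi] * I)
    * (parms[i_k_gm] * G_B - parms[i_k_gm2] * G_M);
  const double glc_AB = parms[i_d_ba] * (1.0 + parms[i_k_ga] * I)
    * (G_B - G_A);
  const double lipolysis = parms[i_beta_f] / (1.0 + parms[i_k_ft] * I * I);
  const double chylo = parms[i_k_a] * (1.0 + parms[i_k_ai] * I) * T_CB;
  const double esterif_A = parms[i_k_aa] * I * A_A * G_A;

  const double aL = parms[i_alpha_L], aM = parms[i_alpha_M],
    aA = parms[i_alpha_A];

  ydot[0] = secretion - parms[i_k_d] * I;
  ydot[1] = (SG - parms[i_k_gl] * G_L + parms[i_k_gl2] * G_B - glucokinase
             - hexokinase_L + parms[i_k_61] * P_L) / aL;
  ydot[2] = (-gsyn_L + gly_L_p - parms[i_k_p] * I * P_L
             + parms[i_k_gp] * L_A + dnl + glucokinase + hexokinase_L
             - parms[i_k_61] * P_L) / aL;
  ydot[3] = (gsyn_L - gly_L_y) / aL;
  ydot[4] = (parms[i_k_pp] * R_M + 2.0 * parms[i_mu_b]
             + parms[i_k_p] * I * P_L - dnl - parms[i_k_al] * I * R_L) / aL;
  ydot[5] = (3.0 * parms[i_k_cl] * T_CB + parms[i_k_bl] * A_B
             + 3.0 * parms[i_k_r] * T_LB + parms[i_k_al] * I * R_L
             - 3.0 * v6sec + 3.0 * tl_rel - 3.0 * v8_al - k7ox) / aL;
  ydot[6] = (v6sec - parms[i_k_9a] * S_L) / aL;
  ydot[7] = (v8_tl - vldl - tl_rel) / aL;
  ydot[8] = (glc_MB - hexokinase_M) / aM;
  ydot[9] = (gsyn_M - gly_M) / aM;
  ydot[10] = (hexokinase_M - gsyn_M + gly_M - parms[i_k_6p] * I * P_M) / aM;
  ydot[11] = (parms[i_k_6p] * I * P_M - parms[i_k_pp] * R_M
              - parms[i_mu_3] * R_M * I * P) / aM;
  ydot[12] = (-3.0 * parms[i_m_s] * I * A_M + 3.0 * parms[i_m_e]
              + 3.0 * parms[i_k_cm] * T_CB + parms[i_k_bm] * A_B
              + 3.0 * parms[i_k_t] * T_LB - parms[i_mu_4] * A_M * P) / aM;
  ydot[13] = (parms[i_m_s] * I * A_M - parms[i_m_e]) / aM;
  ydot[14] = parms[i_mu_amp] - parms[i_mu_4] * A_M * P
    - parms[i_mu_3] * R_M * I * P;
  ydot[15] = (esterif_A - lipolysis) / aA;
  ydot[16] = (-3.0 * esterif_A + 3.0 * chylo + 3.0 * parms[i_k_ba] * T_LB
              + parms[i_k_na] * A_B) / aA;
  ydot[17] = (lipolysis - parms[i_k_gp] * L_A) / aA;
  ydot[18] = (glc_AB - esterif_A) / aA;
  ydot[19] = SF - parms[i_k_cm] * T_CB - parms[i_k_cl] * T_CB - chylo;
  ydot[20] = -parms[i_k_bm] * A_B - parms[i_k_bl] * A_B
    - parms[i_k_na] * A_B + 3.0 * lipolysis + 3.0 * chylo;
  ydot[21] = vldl + parms[i_k_9a] * S_L
    - (parms[i_k_r] + parms[i_k_t] + parms[i_k_ba]) * T_LB;
  ydot[22] = parms[i_k_gl] * G_L - parms[i_k_gl2] * G_B - glc_MB - glc_AB
    - parms[i_mu_1];
}
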