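# Published reference estimates for a Korean Yorkshire nucleus herd analysed
# with this model class. Used as (i) default magnitudes for the synthetic
# herd generator and sampler starting values, and (ii) inputs for the
# plug-in consistency checks of the derived-parameter formulas.

#' Reference variance-component estimates (Yorkshire herd)
#'
#' Posterior-mean variance components and correlations reported for a large
#' Korean Yorkshire herd fitted with the social-effects linear-threshold
#' model (average daily gain with direct and social genetic effects, binary
#' stayability to second parity on the liability scale, and litter size at
#' first parity). Off-diagonal covariances of the 4 x 4 genetic matrix `C`
#' and litter matrix `K` are reconstructed from the reported correlations
#' and variances; the direct-social ADG covariance (5) and the
#' litter/early-life ADG covariance (38) were reported directly and are kept
#' verbatim.
#'
#' @param n_bar average group size the reference analysis used (8.2 pigs).
#' @return A list with elements
#'   * `vs`: variance state (`C`, `K`, `sigma2_g`, `sigma2_e`) usable by
#'     [derived_params()] and as sampler starting values,
#'   * `n_bar`: the average group size,
#'   * `summary`: the reported summary values (phenotypic and total
#'     heritable variances, heritabilities, correlations) for consistency
#'     checks,
#'   * `phenotype_targets`: herd-level phenotype means/SDs (ADG 802 +/- 93
#'     g/d, stayability coded 1/2 with mean 1.85, litter size 10.38 +/- 2.84)
#'     emulated by the synthetic generator.
#' @export
reference_estimates <- function(n_bar = 8.2) {
  gvar <- c(2437, 18, 0.10, 0.80)
  C <- diag(gvar)
  C[1, 2] <- C[2, 1] <- 5
  C[1, 3] <- C[3, 1] <- -0.30 * sqrt(gvar[1] * gvar[3])
  C[1, 4] <- C[4, 1] <- -0.04 * sqrt(gvar[1] * gvar[4])
  C[2, 3] <- C[3, 2] <- 0.04 * sqrt(gvar[2] * gvar[3])
  C[2, 4] <- C[4, 2] <- 0.27 * sqrt(gvar[2] * gvar[4])
  C[3, 4] <- C[4, 3] <- 0.31 * sqrt(gvar[3] * gvar[4])
  dimnames(C) <- list(GEN_EFFECTS, GEN_EFFECTS)

  kvar <- c(249, 32, 0.19, 0.17)
  K <- diag(kvar)
  K[1, 2] <- K[2, 1] <- 38
  K[1, 3] <- K[3, 1] <- -0.38 * sqrt(kvar[1] * kvar[3])
  K[1, 4] <- K[4, 1] <- 0.07 * sqrt(kvar[1] * kvar[4])
  K[2, 3] <- K[3, 2] <- 0.09 * sqrt(kvar[2] * kvar[3])
  K[2, 4] <- K[4, 2] <- 0.05 * sqrt(kvar[2] * kvar[4])
  K[3, 4] <- K[4, 3] <- -0.05 * sqrt(kvar[3] * kvar[4])
  dimnames(K) <- list(LIT_EFFECTS, LIT_EFFECTS)

  list(
    vs = list(C = C, K = K, sigma2_g = 298,
              sigma2_e = c(ADG = 3816, STAY = 1.00, NBA1 = 6.90)),
    n_bar = n_bar,
    summary = list(
      s2_P = c(ADG = 7163, STAY = 1.29, NBA1 = 7.87),
      s2_TBV = 3464,
      T2 = 0.48,
      h2 = c(ADG = 0.34, STAY = 0.07, NBA1 = 0.10),
      r_genetic = c(DBV.ADG_SBV.ADG = 0.03, DBV.ADG_DBV.STAY = -0.30,
                    DBV.ADG_DBV.NBA1 = -0.04, DBV.STAY_DBV.NBA1 = 0.31,
                    SBV.ADG_DBV.STAY = 0.04, SBV.ADG_DBV.NBA1 = 0.27,
                    TBV.ADG_DBV.STAY = -0.23, TBV.ADG_DBV.NBA1 = 0.11),
      r_litter = c(D.ADG_S.ADG = 0.43, D.ADG_D.STAY = -0.38,
                   D.ADG_D.NBA1 = 0.07, D.STAY_D.NBA1 = -0.05,
                   S.ADG_D.STAY = 0.09, S.ADG_D.NBA1 = 0.05),
      social_share_pct = 27),
    phenotype_targets = list(
      adg_mean = 802, adg_sd = 93,
      stay_mean = 1.85, survival = 0.85,
      nba1_mean = 10.38, nba1_sd = 2.84,
      group_size_mean = 8.2, group_size_sd = 2.0,
      group_size_range = c(4L, 14L)))
}
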