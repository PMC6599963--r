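# Derived genetic parameters for the social-effects growth model:
# total breeding values, total heritable variance, phenotypic variance,
# heritabilities and correlations among direct, social and total breeding
# values. All functions are plain arithmetic so they can be applied either
# to posterior means (plug-in mode) or to each posterior sample.

# canonical order of the 4 correlated genetic (and litter) effects:
# 1 = direct ADG, 2 = social ADG, 3 = direct STAY, 4 = direct NBA1
GEN_EFFECTS <- c("aD.ADG", "aS.ADG", "aD.STAY", "aD.NBA1")
LIT_EFFECTS <- c("l.ADG", "k.ADG", "l.STAY", "l.NBA1")
TRAITS <- c("ADG", "STAY", "NBA1")

#' Total breeding value
#'
#' `TBV = a_D + (n_bar - 1) * a_S`: the sum of an animal's direct effect on
#' its own phenotype and its social effect on each of its `n_bar - 1`
#' group mates.
#'
#' @param a_d direct breeding value(s).
#' @param a_s social breeding value(s).
#' @param n_bar average group size.
#' @return Total breeding value(s), vectorised.
#' @export
total_bv <- function(a_d, a_s, n_bar) a_d + (n_bar - 1) * a_s

#' Total heritable variance for a socially affected trait
#'
#' `sigma2_TBV = sigma2_aD + 2 (n_bar - 1) sigma_aDaS + (n_bar - 1)^2 sigma2_aS`,
#' i.e. the quadratic form `w' C_ADG w` with `w = (1, n_bar - 1)`.
#'
#' @param C_adg 2 x 2 genetic covariance block (direct, social) for the
#'   socially affected trait.
#' @param n_bar average group size.
#' @return Scalar total heritable variance.
#' @export
sigma2_tbv <- function(C_adg, n_bar) {
  stopifnot(is.matrix(C_adg), all(dim(C_adg) == 2L))
  w <- c(1, n_bar - 1)
  drop(t(w) %*% C_adg %*% w)
}

#' Phenotypic variance under the social-effects model
#'
#' `sigma2_P = sigma2_aD + (n_bar - 1) sigma2_aS + sigma2_g + sigma2_l +
#'  (n_bar - 1) sigma2_k + sigma2_e`.
#'
#' @param sigma2_aD,sigma2_aS direct and social genetic variances.
#' @param sigma2_g group (pen) variance.
#' @param sigma2_l,sigma2_k birth-litter and social early-life variances.
#' @param sigma2_e residual variance.
#' @param n_bar average group size.
#' @return Scalar phenotypic variance.
#' @export
sigma2_phenotypic <- function(sigma2_aD, sigma2_aS, sigma2_g, sigma2_l,
                              sigma2_k, sigma2_e, n_bar) {
  sigma2_aD + (n_bar - 1) * sigma2_aS + sigma2_g + sigma2_l +
    (n_bar - 1) * sigma2_k + sigma2_e
}

#' Heritabilities and total heritability
#'
#' For the socially affected growth trait: total heritability
#' `T2 = sigma2_TBV / sigma2_P` and classical `h2 = sigma2_aD / sigma2_P`.
#' For the sow traits (binary stayability on the liability scale, litter
#' size): `h2 = sigma2_aD / (sigma2_aD + sigma2_l + sigma2_e)`.
#'
#' @param vs variance state: list with `C` (4 x 4 genetic covariance in the
#'   order direct ADG, social ADG, direct STAY, direct NBA1), `K` (4 x 4
#'   litter covariance, same trait layout), `sigma2_g` and `sigma2_e`
#'   (length-3 named vector ADG, STAY, NBA1).
#' @param n_bar average group size.
#' @return Named vector `(T2, h2_ADG, h2_STAY, h2_NBA1)`.
#' @export
heritabilities <- function(vs, n_bar) {
  C <- vs$C; K <- vs$K
  s2tbv <- sigma2_tbv(C[1:2, 1:2], n_bar)
  s2p <- sigma2_phenotypic(C[1, 1], C[2, 2], vs$sigma2_g, K[1, 1], K[2, 2],
                           vs$sigma2_e[[1L]], n_bar)
  c(T2 = s2tbv / s2p,
    h2_ADG = C[1, 1] / s2p,
    h2_STAY = C[3, 3] / (C[3, 3] + K[3, 3] + vs$sigma2_e[[2L]]),
    h2_NBA1 = C[4, 4] / (C[4, 4] + K[4, 4] + vs$sigma2_e[[3L]]))
}

#' Correlation between total breeding value for growth and a direct
#' breeding value for a reproduction trait
#'
#' `Cov(TBV_ADG, DBV_rep) = sigma_aD(ADG)aD(rep) + (n_bar - 1) * sigma_aD(rep)aS(ADG)`,
#' scaled by `sqrt(sigma2_TBV * sigma2_aD(rep))`.
#'
#' @param C 4 x 4 genetic covariance (order: direct ADG, social ADG,
#'   direct STAY, direct NBA1).
#' @param n_bar average group size.
#' @param rep_trait `"STAY"` or `"NBA1"`.
#' @return Scalar correlation.
#' @export
tbv_dbv_correlation <- function(C, n_bar, rep_trait = c("STAY", "NBA1")) {
  rep_trait <- match.arg(rep_trait)
  r <- if (rep_trait == "STAY") 3L else 4L
  cv <- C[1, r] + (n_bar - 1) * C[2, r]
  cv / sqrt(sigma2_tbv(C[1:2, 1:2], n_bar) * C[r, r])
}

#' Decomposition of the total heritable variance
#'
#' Shares of `sigma2_TBV` attributable to the direct variance, the social
#' variance `(n_bar - 1)^2 sigma2_aS` and the direct-social covariance
#' `2 (n_bar - 1) sigma_aDaS`. When the denominator is the total heritable
#' variance of the same block the three shares sum to one.
#'
#' @param C_adg 2 x 2 genetic covariance block (direct, social).
#' @param n_bar average group size.
#' @param sigma2_TBV optional externally supplied denominator; defaults to
#'   [sigma2_tbv()] of `C_adg`.
#' @return Named vector `(direct, social, covariance)` of shares.
#' @export
variance_shares <- function(C_adg, n_bar, sigma2_TBV = NULL) {
  if (is.null(sigma2_TBV)) sigma2_TBV <- sigma2_tbv(C_adg, n_bar)
  m <- n_bar - 1
  c(direct = C_adg[1, 1],
    social = m^2 * C_adg[2, 2],
    covariance = 2 * m * C_adg[1, 2]) / sigma2_TBV
}

cor_from_cov <- function(M, i, j) M[i, j] / sqrt(M[i, i] * M[j, j])

#' All derived genetic parameters from one variance state
#'
#' Applies every derived-parameter formula to a single variance state
#' (posterior means for plug-in summaries, or one posterior sample when
#' mapped over a chain).
#'
#' @inheritParams heritabilities
#' @return Named numeric vector: total and phenotypic variances, T2 and
#'   heritabilities, the eight genetic correlations among direct, social
#'   and total breeding values, the six litter-environment correlations,
#'   and the variance shares of `sigma2_TBV`.
#' @export
derived_params <- function(vs, n_bar) {
  C <- vs$C; K <- vs$K
  h <- heritabilities(vs, n_bar)
  s2tbv <- sigma2_tbv(C[1:2, 1:2], n_bar)
  s2p <- sigma2_phenotypic(C[1, 1], C[2, 2], vs$sigma2_g, K[1, 1], K[2, 2],
                           vs$sigma2_e[[1L]], n_bar)
  shares <- variance_shares(C[1:2, 1:2], n_bar)
  c(s2_TBV = s2tbv,
    s2_P_ADG = s2p,
    h,
    r_DBV.ADG_SBV.ADG = cor_from_cov(C, 1, 2),
    r_DBV.ADG_DBV.STAY = cor_from_cov(C, 1, 3),
    r_DBV.ADG_DBV.NBA1 = cor_from_cov(C, 1, 4),
    r_DBV.STAY_DBV.NBA1 = cor_from_cov(C, 3, 4),
    r_SBV.ADG_DBV.STAY = cor_from_cov(C, 2, 3),
    r_SBV.ADG_DBV.NBA1 = cor_from_cov(C, 2, 4),
    r_TBV.ADG_DBV.STAY = tbv_dbv_correlation(C, n_bar, "STAY"),
    r_TBV.ADG_DBV.NBA1 = tbv_dbv_correlation(C, n_bar, "NBA1"),
    r_D.ADG_S.ADG = cor_from_cov(K, 1, 2),
    r_D.ADG_D.STAY = cor_from_cov(K, 1, 3),
    r_D.ADG_D.NBA1 = cor_from_cov(K, 1, 4),
    r_D.STAY_D.NBA1 = cor_from_cov(K, 3, 4),
    r_S.ADG_D.STAY = cor_from_cov(K, 2, 3),
    r_S.ADG_D.NBA1 = cor_from_cov(K, 2, 4),
    share_direct = shares[["direct"]],
    share_social = shares[["social"]],
    share_covariance = shares[["covariance"]])
}
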