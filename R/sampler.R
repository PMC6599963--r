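# Multi-trait Gibbs sampler for the linear-threshold social-effects model:
# liability augmentation for stayability, single-site location sweeps
# (compiled kernel), inverse-Wishart updates for the 4 x 4 genetic and
# litter covariance matrices and scaled-inverse-chi-square updates for the
# group and residual variances. The stayability residual variance is fixed
# at 1 (threshold at 0) for identifiability.

#' Sampler starting values
#'
#' Defaults to the reference herd magnitudes, which are on the same scale
#' as the synthetic herd generator.
#'
#' @return Variance state list (`C`, `K`, `sigma2_g`, `sigma2_e`).
#' @export
default_start <- function() reference_estimates()$vs

#' Variance-component priors
#'
#' Weakly-informative default: inverse-Wishart with `nu0 = dim + 2` and
#' scale `S0 = (nu0 - dim - 1) * diag(diag(start))`, so the prior mean
#' equals the starting values; scalar variances get scaled-inverse-chi-square
#' priors with 4 df centred the same way. The `"flat"` option uses
#' `nu0 = -(dim + 1)`, `S0 = 0` (and 0 df for scalars), i.e. posterior
#' updates driven by the data sums of squares alone.
#'
#' @param start variance state providing the centring magnitudes.
#' @param type `"weak"` or `"flat"`.
#' @return List of prior descriptors for the genetic and litter matrices
#'   and the scalar variances.
#' @export
make_priors <- function(start = default_start(), type = c("weak", "flat")) {
  type <- match.arg(type)
  p <- 4L
  if (type == "weak") {
    iw <- function(M) list(nu0 = p + 2, S0 = (p + 2 - p - 1) * diag(diag(M)))
    sc <- function(v) list(df0 = 4, ss0 = 2 * v)
  } else {
    iw <- function(M) list(nu0 = -(p + 1), S0 = matrix(0, p, p))
    sc <- function(v) list(df0 = 0, ss0 = 0)
  }
  list(genetic = iw(start$C), litter = iw(start$K),
       group = sc(start$sigma2_g),
       resid_ADG = sc(start$sigma2_e[[1L]]),
       resid_NBA1 = sc(start$sigma2_e[[3L]]),
       type = type)
}

riwish <- function(df, S) {
  ch <- tryCatch(chol(S), error = function(e)
    stop("inverse-Wishart scale matrix not positive definite (upstream NaN?)"))
  Sinv <- chol2inv(ch)
  W <- stats::rWishart(1L, df, Sinv)[, , 1L]
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

#' Draw the genetic covariance matrix
#'
#' Inverse-Wishart full conditional under the `C (x) A` prior for the
#' animal effects: scale `U' A^{-1} U + S0`, degrees of freedom `N + nu0`.
#'
#' @param U N x 4 matrix of current per-animal genetic effects.
#' @param Ainv sparse A-inverse.
#' @param prior element `genetic` of [make_priors()].
#' @return New 4 x 4 covariance matrix.
#' @export
sample_genetic_covariance <- function(U, Ainv, prior) {
  S <- as.matrix(Matrix::crossprod(U, Ainv %*% U)) + prior$S0
  S <- (S + t(S)) / 2
  riwish(nrow(U) + prior$nu0, S)
}

#' Draw the litter/early-life covariance matrix
#'
#' Inverse-Wishart full conditional under the `K (x) I` prior:
#' scale `L'L + S0`, degrees of freedom `n_litters + nu0`.
#'
#' @param L n_litters x 4 matrix of current litter effects.
#' @param prior element `litter` of [make_priors()].
#' @return New 4 x 4 covariance matrix.
#' @export
sample_litter_covariance <- function(L, prior) {
  S <- crossprod(L) + prior$S0
  S <- (S + t(S)) / 2
  riwish(nrow(L) + prior$nu0, S)
}

#' Draw a scalar variance
#'
#' Scaled-inverse-chi-square full conditional:
#' `(SS + ss0) / rchisq(n + df0)`.
#'
#' @param SS sum of squares of the current effects or residuals.
#' @param n number of contributing terms.
#' @param prior list with `df0` and `ss0`.
#' @return New variance draw.
#' @export
sample_scalar_variance <- function(SS, n, prior) {
  (SS + prior$ss0) / stats::rchisq(1L, n + prior$df0)
}

#' Draw stayability liabilities
#'
#' Truncated-normal draws with unit residual variance and threshold 0:
#' category 1 (culled) from `(-inf, 0)`, category 2 (stayed) from
#' `[0, inf)`, centred at the current linear predictor.
#'
#' @param eta linear predictor(s).
#' @param category stayability code(s), 1 or 2.
#' @return Liability draw(s).
#' @export
sample_liabilities <- function(eta, category) {
  stopifnot(length(eta) == length(category), all(category %in% c(1L, 2L)))
  cpp_rtrunc_liability(as.numeric(eta), as.integer(category))
}

# internal: safe inverses of the current covariance state
varstate_inverses <- function(vs) {
  list(Cinv = chol2inv(chol(vs$C)), Kinv = chol2inv(chol(vs$K)),
       gprec = 1 / vs$sigma2_g)
}

#' One full sweep of location-effect draws
#'
#' Single-site Gibbs updates of every unknown in ascending column order
#' (fixed blocks, genetic block, group, litter block), given the current
#' variance state. Exposed mainly for testing; [run_gibbs()] drives the
#' same kernel.
#'
#' @param system an `sge_system`.
#' @param theta current solution vector.
#' @param e current residual vector (`y - W theta`, liabilities in place of
#'   stayability codes).
#' @param vs current variance state.
#' @return List with updated `theta` and `e`.
#' @export
location_sweep <- function(system, theta, e, vs) {
  theta <- theta + 0 # force copies: the kernel updates in place
  e <- e + 0
  inv <- varstate_inverses(vs)
  rinv <- 1 / vs$sigma2_e[system$data_trait]
  A <- system$Ainv
  cpp_location_sweep(system$W, e, theta, rinv,
                     system$col_type, system$col_unit, system$col_effect,
                     A@p, A@i, A@x, inv$Cinv, inv$Kinv, inv$gprec,
                     as.integer(system$offsets[["genetic"]]),
                     as.integer(system$offsets[["litter"]]))
  list(theta = theta, e = e)
}

#' Run the Gibbs sampler
#'
#' Iterates liability draws, a full location sweep and the variance-component
#' updates; stores the flattened variance state every `thin` iterations
#' after `burnin`. The chain is exactly reproducible from `seed` and the
#' configuration.
#'
#' @param system an `sge_system` from [assemble_system()].
#' @param n_iter total Gibbs rounds.
#' @param burnin rounds discarded before storage begins.
#' @param thin store every `thin`-th post-burn-in round.
#' @param seed RNG seed.
#' @param start starting variance state (default [default_start()]).
#' @param priors `"weak"`, `"flat"`, or a list from [make_priors()].
#' @param fix_variances keep all variance components at `start` (known-
#'   variance sampling of location effects only).
#' @param verbose print progress every 10% of rounds.
#' @return An `sge_chain`: stored samples, posterior-mean solution vector
#'   (`theta_mean`, accumulated over stored rounds), and the run
#'   configuration.
#' @export
run_gibbs <- function(system, n_iter = 20000L, burnin = 10000L, thin = 10L,
                      seed = 1L, start = NULL, priors = "weak",
                      fix_variances = FALSE, verbose = FALSE) {
  stopifnot(burnin < n_iter, thin >= 1L)
  set.seed(seed)
  if (is.null(start)) start <- default_start()
  if (is.character(priors)) priors <- make_priors(start, priors)
  vs <- start
  vs$sigma2_e[[2L]] <- 1 # liability residual fixed

  n_col <- ncol(system$W)
  theta <- numeric(n_col)
  y <- system$y + 0
  srows <- system$stay_data_rows
  scat <- system$stay_cat
  y[srows] <- ifelse(scat == 2L, 0.5, -0.5) # starting liabilities
  e <- y - as.numeric(system$W %*% theta)

  A <- system$Ainv
  gen_cols <- which(system$col_type == 1L)
  grp_cols <- which(system$col_type == 2L)
  lit_cols <- which(system$col_type == 3L)
  adg_rows <- which(system$data_trait == 1L)
  nba_rows <- which(system$data_trait == 3L)

  n_stored <- (n_iter - burnin) %/% thin
  template <- varstate_to_row(vs)
  samples <- matrix(NA_real_, n_stored, length(template),
                    dimnames = list(NULL, names(template)))
  theta_sum <- numeric(n_col)
  stored <- 0L
  gen_off <- as.integer(system$offsets[["genetic"]])
  lit_off <- as.integer(system$offsets[["litter"]])

  for (it in seq_len(n_iter)) {
    inv <- varstate_inverses(vs)
    rinv <- 1 / vs$sigma2_e[system$data_trait]
    if (length(srows)) cpp_sample_liabilities(y, e, srows, scat)
    cpp_location_sweep(system$W, e, theta, rinv,
                       system$col_type, system$col_unit, system$col_effect,
                       A@p, A@i, A@x, inv$Cinv, inv$Kinv, inv$gprec,
                       gen_off, lit_off)
    if (!fix_variances) {
      if (system$n_animals > 0L) {
        U <- matrix(theta[gen_cols], ncol = 4L, byrow = TRUE)
        vs$C <- sample_genetic_covariance(U, A, priors$genetic)
      }
      if (system$n_litters > 0L) {
        L <- matrix(theta[lit_cols], ncol = 4L, byrow = TRUE)
        vs$K <- sample_litter_covariance(L, priors$litter)
      }
      if (system$n_groups > 0L) {
        g <- theta[grp_cols]
        vs$sigma2_g <- sample_scalar_variance(sum(g^2), length(g), priors$group)
      }
      if (length(adg_rows))
        vs$sigma2_e[[1L]] <- sample_scalar_variance(sum(e[adg_rows]^2),
                                                    length(adg_rows),
                                                    priors$resid_ADG)
      if (length(nba_rows))
        vs$sigma2_e[[3L]] <- sample_scalar_variance(sum(e[nba_rows]^2),
                                                    length(nba_rows),
                                                    priors$resid_NBA1)
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      stored <- stored + 1L
      row <- varstate_to_row(vs)
      if (anyNA(row) || any(!is.finite(row)))
        stop("non-finite variance sample at iteration ", it)
      samples[stored, ] <- row
      theta_sum <- theta_sum + theta
    }
    if (verbose && it %% max(1L, n_iter %/% 10L) == 0L)
      message("iteration ", it, "/", n_iter,
              "  s2_aD(ADG) = ", signif(vs$C[1, 1], 4),
              "  s2_aS(ADG) = ", signif(vs$C[2, 2], 4))
  }
  chain <- new_chain(samples, n_bar = system$n_bar,
                     config = list(n_iter = n_iter, burnin = burnin,
                                   thin = thin, seed = seed,
                                   priors = priors$type,
                                   fix_variances = fix_variances))
  chain$theta_mean <- theta_sum / max(stored, 1L)
  chain$dims <- list(n_animals = system$n_animals, n_groups = system$n_groups,
                     n_litters = system$n_litters,
                     n_records = system$n_records)
  chain
}
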