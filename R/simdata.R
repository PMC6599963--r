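# Synthetic herd generator: discrete-generation pedigree, pens of 4-14
# same-sex pigs, birth litters, and phenotypes generated under the exact
# social-effects linear-threshold model with known parameters, so that the
# whole pipeline can be exercised and parameter recovery tested without
# any external data.

#' Simulation scenario
#'
#' Bundles the structural sizes, the true variance components and the
#' fixed-effect magnitudes for [simulate_herd()]. The default `"desk"`
#' scenario produces roughly 1,800 growth-tested pigs and 700 sows in a
#' 2-generation pedigree; `"tiny"` is a ~60-animal smoke-test herd and
#' `"full"` approaches the scale of a real nucleus herd. True variance
#' components default to the reference herd magnitudes, phenotype means to
#' the reference targets (growth 802 g/d, survival to second parity 0.85,
#' litter size 10.38).
#'
#' @param size `"desk"`, `"tiny"` or `"full"`.
#' @param ... named overrides of any scenario field.
#' @return An `sge_scenario` list.
#' @export
herd_scenario <- function(size = c("desk", "tiny", "full"), ...) {
  size <- match.arg(size)
  ref <- reference_estimates()
  base <- list(
    size = size,
    n_sires = 25L, n_dams = 100L,
    litters_per_gen = c(100L, 110L),
    litter_size_range = c(6L, 14L), litter_size_mean = 10.3,
    pen_size_range = c(4L, 14L), pen_size_mean = 8.2, pen_size_sd = 2.0,
    n_bar = 8.2,
    p_test = 0.85,  # fraction of pigs entering the growth test (penned)
    p_sow = 0.70,   # fraction of females recorded for the sow traits
    true = ref$vs,
    adg_mu = 802, sex_effect = 20, n_birth_ym = 8, birth_ym_sd = 20,
    age_mu = 155, age_sd = 6, age_tbv_slope = -0.03,
    b_age = -2, b_age2 = -0.01,
    survival = 0.85, n_farrow_ym = 6, farrow_ym_sd = 0.05,
    nba_mu = 10.38, nba_ym_sd = 0.3)
  if (size == "tiny") {
    base$n_sires <- 5L; base$n_dams <- 14L
    base$litters_per_gen <- 6L
    base$litter_size_range <- c(5L, 9L); base$litter_size_mean <- 7
    base$pen_size_range <- c(4L, 8L); base$pen_size_mean <- 5.5
    base$pen_size_sd <- 1.0
    base$n_birth_ym <- 3L; base$n_farrow_ym <- 2L
  } else if (size == "full") {
    base$n_sires <- 60L; base$n_dams <- 900L
    base$litters_per_gen <- c(900L, 900L, 900L)
  }
  override <- list(...)
  bad <- setdiff(names(override), names(base))
  if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  base[names(override)] <- override
  stopifnot(base$pen_size_range[1L] >= 2L,
            base$survival > 0, base$survival < 1,
            all(eigen(base$true$C, only.values = TRUE)$values > 0),
            all(eigen(base$true$K, only.values = TRUE)$values > 0))
  structure(base, class = "sge_scenario")
}

sample_sizes_in_range <- function(n, mean, sd, range) {
  s <- as.integer(round(stats::rnorm(n, mean, sd)))
  pmin(pmax(s, range[1L]), range[2L])
}

#' Simulate a discrete-generation pedigree with litters
#'
#' Founders (sires and dams), then per generation one sire x dam mating per
#' litter with litter sizes drawn from a truncated Poisson. Parents of
#' later generations are sampled from the previous one, so every
#' non-founder has both parents known.
#'
#' @param scenario an `sge_scenario`.
#' @param seed RNG seed.
#' @return List: `ped` (sorted `sge_pedigree`) and `meta` (data frame with
#'   animal, generation, sex, birth litter, parents).
#' @export
simulate_pedigree <- function(scenario, seed = 1L) {
  set.seed(seed)
  sc <- scenario
  rng <- sc$litter_size_range[1L]:sc$litter_size_range[2L]
  size_probs <- stats::dpois(rng, sc$litter_size_mean)
  size_probs <- size_probs / sum(size_probs)

  sires <- sprintf("S%03d", seq_len(sc$n_sires))
  dams <- sprintf("D%04d", seq_len(sc$n_dams))
  meta <- data.frame(animal = c(sires, dams),
                     sex = c(rep("M", sc$n_sires), rep("F", sc$n_dams)),
                     generation = 0L, litter = NA_character_,
                     sire = NA_character_, dam = NA_character_,
                     stringsAsFactors = FALSE)
  pool_m <- sires; pool_f <- dams
  for (g in seq_along(sc$litters_per_gen)) {
    nl <- sc$litters_per_gen[g]
    lit_sire <- sample(pool_m, nl, replace = TRUE)
    lit_dam <- if (length(pool_f) >= nl) sample(pool_f, nl)
               else sample(pool_f, nl, replace = TRUE)
    sizes <- if (length(rng) == 1L) rep(rng, nl)
             else sample(rng, nl, replace = TRUE, prob = size_probs)
    n_off <- sum(sizes)
    off <- sprintf("G%d_%04d", g, seq_len(n_off))
    lit_id <- sprintf("L%d_%03d", g, seq_len(nl))
    gen_meta <- data.frame(animal = off,
                           sex = sample(c("M", "F"), n_off, replace = TRUE),
                           generation = g,
                           litter = rep(lit_id, sizes),
                           sire = rep(lit_sire, sizes),
                           dam = rep(lit_dam, sizes),
                           stringsAsFactors = FALSE)
    meta <- rbind(meta, gen_meta)
    pool_m <- sample(gen_meta$animal[gen_meta$sex == "M"],
                     min(sc$n_sires, sum(gen_meta$sex == "M")))
    pool_f <- gen_meta$animal[gen_meta$sex == "F"]
  }
  ped <- as_pedigree(meta[, c("animal", "sire", "dam")])
  meta <- meta[match(ped$labels, meta$animal), ]
  rownames(meta) <- NULL
  list(ped = ped, meta = meta)
}

#' Simulate correlated breeding values down a pedigree
#'
#' Founders are drawn from `MVN(0, C)`; a non-founder is the parent average
#' plus a Mendelian-sampling deviation `MVN(0, C * (0.5 - 0.25 (F_s + F_d)))`,
#' so that the stacked effects have covariance `C (x) A`.
#'
#' @param ped a sorted `sge_pedigree`.
#' @param C 4 x 4 genetic covariance matrix.
#' @param seed RNG seed.
#' @return N x 4 matrix of genetic effects (direct ADG, social ADG,
#'   direct STAY, direct NBA1).
#' @export
simulate_breeding_values <- function(ped, C, seed = 1L) {
  set.seed(seed)
  n <- n_animals(ped)
  F <- inbreeding(ped)
  Lc <- t(chol(C))
  U <- matrix(0, n, 4L)
  Z <- matrix(stats::rnorm(4L * n), n, 4L)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s > 0L && d > 0L) {
      mv <- 0.5 - 0.25 * (F[s] + F[d])
      U[i, ] <- 0.5 * (U[s, ] + U[d, ]) + sqrt(mv) * drop(Lc %*% Z[i, ])
    } else if (s > 0L || d > 0L) {
      p <- max(s, d)
      mv <- 0.75 - 0.25 * F[p]
      U[i, ] <- 0.5 * U[p, ] + sqrt(mv) * drop(Lc %*% Z[i, ])
    } else {
      U[i, ] <- drop(Lc %*% Z[i, ])
    }
  }
  colnames(U) <- GEN_EFFECTS
  U
}

# cut a vector of animals into pens with sizes drawn around the target mean;
# a short remainder is folded into the preceding pens
assign_pens <- function(ids, scenario, prefix) {
  n <- length(ids)
  sizes <- integer(0)
  while (sum(sizes) < n) {
    s <- sample_sizes_in_range(1L, scenario$pen_size_mean,
                               scenario$pen_size_sd, scenario$pen_size_range)
    sizes <- c(sizes, s)
  }
  over <- sum(sizes) - n
  sizes[length(sizes)] <- sizes[length(sizes)] - over
  while (sizes[length(sizes)] < scenario$pen_size_range[1L] && length(sizes) > 1L) {
    short <- sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
    room <- which(sizes < scenario$pen_size_range[2L])
    for (k in seq_len(short)) {
      if (!length(room)) room <- seq_along(sizes)
      j <- room[1 + (k - 1) %% length(room)]
      sizes[j] <- sizes[j] + 1L
    }
  }
  rep(sprintf("%s_P%03d", prefix, seq_along(sizes)), sizes)
}

#' Simulate phenotypes under the social-effects model
#'
#' Tested pigs are penned with same-sex, same-generation mates; growth is
#' the sum of fixed effects (sex, birth year-month, age and age-squared
#' covariates), the pig's direct genetic effect, the dilution-weighted
#' social effects of its pen mates, the pen effect, its birth-litter
#' effect, the dilution-weighted early-life effects of its mates' birth
#' litters, and a residual. Stayability is generated on the liability
#' scale (unit residual, threshold at zero, fixed-effect level solved from
#' the target survival rate) and coded 1/2; litter size is a rounded
#' Gaussian floored at zero. Sow traits are recorded for a configurable
#' fraction of females. Days to target weight decrease in the pig's total
#' breeding value, creating realistic covariate confounding.
#'
#' @param sim output of [simulate_pedigree()].
#' @param bv breeding-value matrix from [simulate_breeding_values()].
#' @param scenario an `sge_scenario`.
#' @param seed RNG seed.
#' @return List: `records` (phenotype data frame in the [load_phenotypes()]
#'   dialect) and `truth` (all generated effect realisations).
#' @export
simulate_phenotypes <- function(sim, bv, scenario, seed = 1L) {
  set.seed(seed)
  sc <- scenario
  meta <- sim$meta
  n <- nrow(meta)
  recorded_gen <- meta$generation > 0L

  lit_ids <- unique(meta$litter[!is.na(meta$litter)])
  lit_eff <- matrix(stats::rnorm(4L * length(lit_ids)), length(lit_ids), 4L) %*%
    chol(sc$true$K)
  rownames(lit_eff) <- lit_ids
  colnames(lit_eff) <- LIT_EFFECTS
  lit_of <- match(meta$litter, lit_ids)

  tested <- recorded_gen & stats::runif(n) < sc$p_test
  pen <- rep(NA_character_, n)
  for (g in unique(meta$generation[tested])) {
    for (sx in c("M", "F")) {
      idx <- which(tested & meta$generation == g & meta$sex == sx)
      if (length(idx) < sc$pen_size_range[1L]) { tested[idx] <- FALSE; next }
      idx <- sample(idx)
      pen[idx] <- assign_pens(idx, sc, sprintf("G%d%s", g, sx))
    }
  }
  pens <- unique(pen[!is.na(pen)])
  pen_eff <- stats::rnorm(length(pens), 0, sqrt(sc$true$sigma2_g))
  names(pen_eff) <- pens

  ym_levels <- sprintf("YM%02d", seq_len(sc$n_birth_ym))
  ym_eff <- stats::rnorm(sc$n_birth_ym, 0, sc$birth_ym_sd)
  ym_eff <- ym_eff - mean(ym_eff)
  names(ym_eff) <- ym_levels
  lit_ym <- sample(ym_levels, length(lit_ids), replace = TRUE)
  names(lit_ym) <- lit_ids

  tbv <- total_bv(bv[, 1L], bv[, 2L], sc$n_bar)
  age <- sc$age_mu + sc$age_tbv_slope * (tbv - mean(tbv)) +
    stats::rnorm(n, 0, sc$age_sd)

  adg <- rep(NA_real_, n)
  group_size <- rep(NA_integer_, n)
  soc_gen <- rep(NA_real_, n) # dilution-weighted mate social genetic load
  soc_lit <- rep(NA_real_, n)
  for (p in pens) {
    mem <- which(!is.na(pen) & pen == p)
    ng <- length(mem)
    d <- dilution_factor(ng, sc$n_bar)
    sum_as <- sum(bv[mem, 2L])
    sum_k <- sum(lit_eff[lit_of[mem], 2L])
    for (a in mem) {
      soc_gen[a] <- d * (sum_as - bv[a, 2L])
      soc_lit[a] <- d * (sum_k - lit_eff[lit_of[a], 2L])
    }
    group_size[mem] <- ng
  }
  ti <- which(!is.na(pen))
  fixed_adg <- sc$adg_mu +
    ifelse(meta$sex == "M", sc$sex_effect / 2, -sc$sex_effect / 2) +
    ym_eff[lit_ym[meta$litter]] +
    sc$b_age * (age - sc$age_mu) + sc$b_age2 * (age - sc$age_mu)^2
  e_adg <- stats::rnorm(n, 0, sqrt(sc$true$sigma2_e[[1L]]))
  adg[ti] <- fixed_adg[ti] + bv[ti, 1L] + soc_gen[ti] +
    pen_eff[pen[ti]] + lit_eff[lit_of[ti], 1L] + soc_lit[ti] + e_adg[ti]

  # sow traits on a fraction of females of the recorded generations
  sow <- recorded_gen & meta$sex == "F" & stats::runif(n) < sc$p_sow
  fym_levels <- sprintf("FYM%02d", seq_len(sc$n_farrow_ym))
  liab_sd <- sqrt(sc$true$C[3, 3] + sc$true$K[3, 3] + 1)
  stay_mu <- stats::qnorm(sc$survival) * liab_sd
  fym_eff <- stats::rnorm(sc$n_farrow_ym, 0, sc$farrow_ym_sd)
  fym_eff <- fym_eff - mean(fym_eff)
  nba_ym_eff <- stats::rnorm(sc$n_farrow_ym, 0, sc$nba_ym_sd)
  nba_ym_eff <- nba_ym_eff - mean(nba_ym_eff)
  names(fym_eff) <- names(nba_ym_eff) <- fym_levels
  farrow_ym <- rep(NA_character_, n)
  stay <- rep(NA_integer_, n)
  nba1 <- rep(NA_real_, n)
  si <- which(sow)
  farrow_ym[si] <- sample(fym_levels, length(si), replace = TRUE)
  liab <- stay_mu + fym_eff[farrow_ym[si]] + bv[si, 3L] +
    lit_eff[lit_of[si], 3L] + stats::rnorm(length(si))
  stay[si] <- ifelse(liab >= 0, 2L, 1L)
  nba <- sc$nba_mu + nba_ym_eff[farrow_ym[si]] + bv[si, 4L] +
    lit_eff[lit_of[si], 4L] +
    stats::rnorm(length(si), 0, sqrt(sc$true$sigma2_e[[3L]]))
  nba1[si] <- pmax(round(nba), 0)

  keep <- ti_or_sow <- !is.na(adg) | !is.na(stay) | !is.na(nba1)
  records <- data.frame(
    animal = meta$animal, sex = meta$sex,
    birth_ym = ifelse(is.na(meta$litter), NA_character_, lit_ym[meta$litter]),
    group = pen, group_size = group_size, litter = meta$litter,
    age = round(age, 1), adg = round(adg, 1),
    farrow_ym = farrow_ym, stay = stay, nba1 = nba1,
    stringsAsFactors = FALSE)[keep, ]
  rownames(records) <- NULL
  truth <- list(bv = bv, litter_effects = lit_eff, pen_effects = pen_eff,
                ym_effects = ym_eff, fym_effects = fym_eff,
                social_genetic = soc_gen, social_litter = soc_lit,
                liability_mu = stay_mu, tested = tested, sow = sow,
                scenario = sc)
  list(records = records, truth = truth)
}

#' Simulate a complete herd
#'
#' Pedigree, breeding values and phenotypes in one call; sub-seeds are
#' derived deterministically from `seed`.
#'
#' @param scenario an `sge_scenario`.
#' @param seed master RNG seed.
#' @return List: `ped`, `meta`, `records`, `truth`.
#' @export
simulate_herd <- function(scenario, seed = 1L) {
  sim <- simulate_pedigree(scenario, seed = seed)
  bv <- simulate_breeding_values(sim$ped, scenario$true$C, seed = seed + 1L)
  ph <- simulate_phenotypes(sim, bv, scenario, seed = seed + 2L)
  list(ped = sim$ped, meta = sim$meta, records = ph$records, truth = ph$truth)
}

#' Write a benchmark data bundle
#'
#' Pedigree and phenotype files in the package dialects plus a structured
#' truth file listing every generating parameter.
#'
#' @param scenario an `sge_scenario` (or a size keyword for
#'   [herd_scenario()]).
#' @param dir output directory (created if needed).
#' @param seed master RNG seed.
#' @return Named paths of the written files, invisibly.
#' @export
make_benchmark_dataset <- function(scenario = "desk", dir, seed = 1L) {
  if (is.character(scenario)) scenario <- herd_scenario(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  herd <- simulate_herd(scenario, seed = seed)
  paths <- c(pedigree = file.path(dir, "pedigree.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.yaml"))
  write_pedigree(herd$ped, paths[["pedigree"]])
  write_phenotypes(herd$records, paths[["phenotypes"]])
  truth <- list(seed = seed, size = scenario$size, n_bar = scenario$n_bar,
                C = as.vector(scenario$true$C), K = as.vector(scenario$true$K),
                sigma2_g = scenario$true$sigma2_g,
                sigma2_e = as.list(scenario$true$sigma2_e),
                survival = scenario$survival,
                adg_mu = scenario$adg_mu, nba_mu = scenario$nba_mu)
  yaml::write_yaml(truth, paths[["truth"]])
  invisible(paths)
}
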