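test_that("simulated pedigree bookkeeping, determinism and ordering", {
  sc <- herd_scenario("tiny")
  one <- simulate_pedigree(herd_scenario("tiny", litters_per_gen = 2L,
                                         litter_size_range = c(4L, 4L),
                                         litter_size_mean = 4),
                           seed = 1)
  expect_equal(sum(one$meta$generation > 0L), 8L) # 2 litters of exactly 4
  a <- simulate_pedigree(sc, seed = 5)
  b <- simulate_pedigree(sc, seed = 5)
  expect_identical(a$ped$labels, b$ped$labels)
  expect_identical(a$meta, b$meta)
  ped <- a$ped
  expect_identical(topological_sort(ped)$labels, ped$labels)
  non_founder <- ped$sire[ped$sire > 0L | ped$dam > 0L]
  expect_true(all(ped$sire[ped$dam > 0L] > 0L)) # both parents known together
})

test_that("founder breeding values reproduce the scenario covariance", {
  n <- 8000L
  ped <- as_pedigree(data.frame(animal = sprintf("f%04d", 1:n),
                                sire = "0", dam = "0"))
  C <- reference_estimates()$vs$C
  U <- simulate_breeding_values(ped, C, seed = 2)
  emp <- stats::cov(U)
  expect_equal(diag(emp), diag(C), tolerance = 0.05, ignore_attr = TRUE)
  expect_lt(max(abs(emp - C) / sqrt(diag(C) %o% diag(C))), 0.05)
})

test_that("breeding values follow C (x) A down a small pedigree", {
  sc <- herd_scenario("tiny", litters_per_gen = 4L)
  sim <- simulate_pedigree(sc, seed = 3)
  ped <- sim$ped
  n <- n_animals(ped)
  A <- tabular_A(ped)
  C <- reference_estimates()$vs$C
  reps <- 3000L
  acc <- array(0, c(n, 4L, reps))
  for (r in seq_len(reps))
    acc[, , r] <- simulate_breeding_values(ped, C, seed = 1000L + r)
  # parent-offspring regression: conditional mean is the parent average
  off <- which(ped$sire > 0L & ped$dam > 0L)
  i <- off[1L]
  mid <- 0.5 * (acc[ped$sire[i], 1L, ] + acc[ped$dam[i], 1L, ])
  fit <- stats::lm(acc[i, 1L, ] ~ mid)
  expect_equal(unname(stats::coef(fit)[2L]), 1, tolerance = 0.1)
  # empirical covariance of the direct-growth effect across animals ~ C11 * A
  emp <- stats::cov(t(acc[, 1L, ]))
  expect_lt(max(abs(emp - C[1, 1] * A)) / C[1, 1], 0.12)
  # cross-effect, cross-animal: cov(u1_i, u3_j) ~ C13 * A_ij
  j <- ped$sire[i]
  emp13 <- stats::cov(acc[i, 1L, ], acc[j, 3L, ])
  expect_equal(emp13, C[1, 3] * A[i, j], tolerance = 0.35)
})

test_that("desk-scale phenotype moments hit the herd targets", {
  herd <- simulate_herd(herd_scenario("desk"), seed = 11)
  rec <- herd$records
  adg <- rec$adg[!is.na(rec$adg)]
  expect_gt(length(adg), 1200L)
  expect_equal(mean(adg), 802, tolerance = 10 / 802)
  expect_equal(stats::sd(adg), 93, tolerance = 0.10)
  stay <- rec$stay[!is.na(rec$stay)]
  expect_gt(length(stay), 400L)
  surv <- mean(stay == 2L)
  expect_lt(abs(surv - 0.85), 3 * sqrt(0.85 * 0.15 / length(stay)) + 0.01)
  nba <- rec$nba1[!is.na(rec$nba1)]
  expect_equal(mean(nba), 10.38, tolerance = 0.35 / 10.38)
  sizes <- rec$group_size[!is.na(rec$group_size)]
  expect_true(all(sizes >= 4L & sizes <= 14L))
  # pen-level mean size (animal-level averages are size-biased upward)
  pen_sizes <- tapply(sizes, rec$group[!is.na(rec$group)], `[`, 1L)
  expect_equal(mean(pen_sizes), 8.2, tolerance = 0.6 / 8.2)
})

test_that("doubling the social variance doubles the social phenotype load", {
  sc1 <- herd_scenario("desk", litters_per_gen = c(60L))
  C2 <- sc1$true$C
  C2[2, 2] <- 4 * C2[2, 2]
  C2[2, -2] <- C2[-2, 2] <- 2 * C2[2, -2] # keep correlations, double the SD
  sc2 <- herd_scenario("desk", litters_per_gen = c(60L),
                       true = utils::modifyList(sc1$true, list(C = C2)))
  h1 <- simulate_herd(sc1, seed = 4)
  h2 <- simulate_herd(sc2, seed = 4)
  v1 <- stats::var(h1$truth$social_genetic, na.rm = TRUE)
  v2 <- stats::var(h2$truth$social_genetic, na.rm = TRUE)
  expect_equal(v2 / v1, 4, tolerance = 0.25)
})

test_that("zeroing all random effects leaves exactly the fixed growth curve", {
  zero <- list(C = diag(1e-12, 4), K = diag(1e-12, 4), sigma2_g = 1e-12,
               sigma2_e = c(ADG = 1e-12, STAY = 1, NBA1 = 1e-12))
  sc <- herd_scenario("tiny", true = zero)
  herd <- simulate_herd(sc, seed = 6)
  rec <- herd$records
  tested <- !is.na(rec$adg)
  sexeff <- ifelse(rec$sex == "M", sc$sex_effect / 2, -sc$sex_effect / 2)
  ym <- herd$truth$ym_effects[rec$birth_ym]
  agec <- rec$age - sc$age_mu
  fixed <- sc$adg_mu + sexeff + ym + sc$b_age * agec + sc$b_age2 * agec^2
  expect_equal(rec$adg[tested], unname(fixed[tested]), tolerance = 0.002)
})

test_that("benchmark bundles load through the whole pipeline deterministically", {
  dir <- tempfile("bundle")
  paths <- make_benchmark_dataset("tiny", dir, seed = 9)
  expect_true(all(file.exists(paths)))
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(matrix(unlist(truth$C), 4), unname(reference_estimates()$vs$C),
               tolerance = 1e-6)
  ped <- read_pedigree(paths[["pedigree"]])
  rec <- load_phenotypes(paths[["phenotypes"]], ped)
  groups <- build_groups(rec, n_bar = truth$n_bar)
  sys <- assemble_system(rec, groups, ped)
  ch <- run_gibbs(sys, n_iter = 60L, burnin = 20L, thin = 2L, seed = 1)
  expect_equal(nrow(ch$samples), 20L)
  dir2 <- tempfile("bundle")
  paths2 <- make_benchmark_dataset("tiny", dir2, seed = 9)
  expect_identical(readLines(paths[["phenotypes"]]),
                   readLines(paths2[["phenotypes"]]))
})
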