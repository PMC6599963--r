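test_that("dilution factor follows the printed formula", {
  expect_equal(dilution_factor(8.2, 8.2), 1.0)
  expect_equal(dilution_factor(3, 8.2), 3.6)
  expect_equal(dilution_factor(14, 8.2), 7.2 / 13)
  expect_error(dilution_factor(1, 8.2), "size < 2")
})

test_that("phenotype loading validates animals, STAY codes and group presence", {
  fx <- tiny_system()
  rec <- fx$rec
  expect_s3_class(rec, "sge_records")
  bad <- fx$herd$records
  bad$animal[1] <- "NOT_IN_PED"
  expect_error(as_herd_records(bad, fx$herd$ped), "not in pedigree")
  bad2 <- fx$herd$records
  sow <- which(!is.na(bad2$stay))[1]
  bad2$stay[sow] <- 3
  expect_error(as_herd_records(bad2, fx$herd$ped), "STAY must be 1")
  bad3 <- fx$herd$records
  adg_row <- which(!is.na(bad3$adg))[1]
  bad3$group[adg_row] <- NA
  expect_error(as_herd_records(bad3, fx$herd$ped), "without a group")
})

test_that("phenotypes round-trip through file with masks intact", {
  fx <- tiny_system()
  path <- tempfile(fileext = ".tsv")
  write_phenotypes(fx$herd$records, path)
  back <- load_phenotypes(path, fx$herd$ped)
  expect_equal(back$adg, fx$rec$adg)
  expect_equal(back$stay, fx$rec$stay)
  expect_equal(back$litter_code, fx$rec$litter_code)
  expect_identical(is.na(back$nba1), is.na(fx$rec$nba1))
})

test_that("trait cross-tabulation matches the simulator bookkeeping", {
  fx <- tiny_system()
  tab <- cross_tabulate_traits(fx$rec)
  rec <- fx$rec
  expect_equal(tab["ADG", "ADG"], sum(!is.na(rec$adg)))
  expect_equal(tab["STAY", "STAY"], sum(!is.na(rec$stay)))
  expect_equal(tab["NBA1", "NBA1"], sum(!is.na(rec$nba1)))
  expect_equal(tab["ADG", "STAY"], sum(!is.na(rec$adg) & !is.na(rec$stay)))
  truth <- fx$herd$truth
  expect_equal(unname(tab["ADG", "ADG"]), sum(truth$tested))
  expect_equal(unname(tab["STAY", "STAY"]), sum(truth$sow))
  empty <- fx$rec[0, ]
  attr(empty, "litter_levels") <- character(0)
  expect_true(all(cross_tabulate_traits(empty) == 0))
})

test_that("social incidence rows sum to n_bar - 1 and skip the own animal", {
  fx <- tiny_system()
  ZS <- build_social_incidence(fx$rec, fx$groups)
  rs <- Matrix::rowSums(ZS)
  expect_true(all(abs(rs - 7.2) < 1e-10))
  adg_rows <- which(!is.na(fx$rec$adg))
  own <- ZS[cbind(seq_along(adg_rows), fx$rec$code[adg_rows])]
  expect_true(all(own == 0))
})

test_that("a pen of two with n_bar 8.2 puts 7.2 on the single mate", {
  ped <- as_pedigree(data.frame(animal = c("a", "b"), sire = 0, dam = 0))
  df <- data.frame(animal = c("a", "b"), sex = "M", birth_ym = "y1",
                   group = "p1", group_size = 2L, litter = c("L1", "L2"),
                   age = c(150, 160), adg = c(800, 810),
                   farrow_ym = NA, stay = NA, nba1 = NA,
                   stringsAsFactors = FALSE)
  rec <- as_herd_records(df, ped)
  groups <- build_groups(rec, n_bar = 8.2)
  ZS <- build_social_incidence(rec, groups)
  expect_equal(ZS[1, rec$code[2]], 7.2)
  expect_equal(ZS[2, rec$code[1]], 7.2)
  expect_equal(Matrix::nnzero(ZS), 2)
})

test_that("mate-litter incidence aggregates full sibs and sums to n_bar - 1", {
  # pen of 3 where animals b and c are full sibs from litter L2
  ped <- as_pedigree(data.frame(animal = c("a", "b", "c"), sire = 0, dam = 0))
  df <- data.frame(animal = c("a", "b", "c"), sex = "M", birth_ym = "y1",
                   group = "p1", group_size = 3L,
                   litter = c("L1", "L2", "L2"),
                   age = 150, adg = 800, farrow_ym = NA, stay = NA, nba1 = NA,
                   stringsAsFactors = FALSE)
  rec <- as_herd_records(df, ped)
  groups <- build_groups(rec, n_bar = 8.2)
  Q <- build_social_litter_incidence(rec, groups)
  d <- dilution_factor(3, 8.2)
  lit2 <- rec$litter_code[2]
  expect_equal(Q[1, lit2], 2 * d)     # both mates of a are from L2
  expect_equal(Q[2, lit2], d)         # b sees its own litter via mate c
  expect_equal(unname(Matrix::rowSums(Q)), rep(7.2, 3))
  Qx <- build_social_litter_incidence(rec, groups, own_litter = FALSE)
  expect_equal(Qx[2, lit2], 0)        # own-litter mates excluded on request
  fx <- tiny_system()
  Qt <- build_social_litter_incidence(fx$rec, fx$groups)
  expect_true(all(abs(Matrix::rowSums(Qt) - 7.2) < 1e-10))
})

test_that("fixed-effect encoding: levels, covariate centring, 11 size classes", {
  fx <- tiny_system()
  enc <- encode_fixed_effects(fx$rec, "ADG")
  n_ym <- length(unique(fx$rec$birth_ym[enc$rows]))
  n_sex <- length(unique(fx$rec$sex[enc$rows]))
  n_gs <- length(unique(bin_group_size(fx$rec$group_size[enc$rows])))
  expect_equal(ncol(enc$X), n_ym + n_sex + n_gs + 2L)
  age_col <- enc$X[, ncol(enc$X) - 1L]
  expect_equal(sum(age_col), 0, tolerance = 1e-8)
  # all sizes 4..14 present gives 11 singleton classes
  expect_equal(length(unique(bin_group_size(4:14))), 11L)
  expect_equal(bin_group_size(c(2, 20)), c(4L, 14L))
  enc_s <- encode_fixed_effects(fx$rec, "STAY")
  expect_equal(ncol(enc_s$X), length(unique(fx$rec$farrow_ym[enc_s$rows])))
})

test_that("assembled system partitions columns and covers all pedigree animals", {
  fx <- tiny_system()
  sys <- fx$system
  expect_equal(ncol(sys$W), sum(sys$widths))
  expect_equal(sum(sys$widths), length(sys$col_type))
  expect_equal(sum(sys$col_type == 1L), 4L * n_animals(fx$herd$ped))
  expect_equal(sum(sys$col_type == 3L), 4L * sys$n_litters)
  expect_equal(length(sys$y), sum(sys$n_records))
  # trio with one ADG record still carries a 4-effect genetic block per animal
  ped <- as_pedigree(trio_df())
  df <- data.frame(animal = c("o", "s"), sex = "M", birth_ym = "y1",
                   group = "p1", group_size = 2L, litter = "L1",
                   age = c(150, 152), adg = c(800, 790),
                   farrow_ym = NA, stay = NA, nba1 = NA,
                   stringsAsFactors = FALSE)
  rec <- as_herd_records(df, ped)
  sys2 <- assemble_system(rec, build_groups(rec), ped)
  expect_equal(unname(sys2$widths[["genetic"]]), 12L)
})
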