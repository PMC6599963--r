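# Model layout: phenotype records, pen (group) structure with dilution
# weights, sparse incidence structures for direct, social, group,
# birth-litter and social early-life effects, and assembly of the full
# multi-trait equation system.

#' Validate and recode a phenotype table
#'
#' @param df data frame with columns `animal`, `sex`, `birth_ym`, `group`,
#'   `group_size`, `litter`, `age`, `adg`, `farrow_ym`, `stay`, `nba1`
#'   (missing values as `NA`).
#' @param ped the `sge_pedigree` the records belong to.
#' @return An `sge_records` data frame: the input plus integer `code`
#'   (pedigree position) and `litter_code` columns, with litter levels
#'   assigned in first-appearance order across all traits (growth and sow
#'   records share one birth-litter level set).
#' @export
as_herd_records <- function(df, ped) {
  needed <- c("animal", "sex", "birth_ym", "group", "group_size", "litter",
              "age", "adg", "farrow_ym", "stay", "nba1")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  rec <- df[, needed]
  rec$animal <- as.character(rec$animal)
  rec$code <- match(rec$animal, ped$labels)
  if (anyNA(rec$code))
    stop("animal(s) not in pedigree: ",
         paste(unique(rec$animal[is.na(rec$code)]), collapse = ", "))
  bad_stay <- !is.na(rec$stay) & !(rec$stay %in% c(1, 2))
  if (any(bad_stay))
    stop("STAY must be 1 (culled) or 2 (stayed); offending animal(s): ",
         paste(rec$animal[bad_stay], collapse = ", "))
  if (any(!is.na(rec$adg) & is.na(rec$group)))
    stop("ADG record(s) without a group id: ",
         paste(rec$animal[!is.na(rec$adg) & is.na(rec$group)], collapse = ", "))
  if (any(is.na(rec$adg) & !is.na(rec$group)))
    stop("group id present for record(s) without ADG: ",
         paste(rec$animal[is.na(rec$adg) & !is.na(rec$group)], collapse = ", "))
  has_obs <- !is.na(rec$adg) | !is.na(rec$stay) | !is.na(rec$nba1)
  no_lit <- has_obs & is.na(rec$litter)
  if (any(no_lit))
    stop("missing birth litter for recorded animal(s): ",
         paste(rec$animal[no_lit], collapse = ", "))
  lit_levels <- unique(rec$litter[!is.na(rec$litter)])
  rec$litter_code <- match(rec$litter, lit_levels)
  attr(rec, "litter_levels") <- lit_levels
  class(rec) <- c("sge_records", "data.frame")
  rec
}

#' Load a phenotype file
#'
#' Tab-delimited text with the named columns of [as_herd_records()];
#' empty cells are missing values.
#'
#' @param path phenotype file path.
#' @param ped the `sge_pedigree` the records belong to.
#' @return An `sge_records` data frame.
#' @export
load_phenotypes <- function(path, ped) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          colClasses = list(animal = "character",
                                            litter = "character")[c("animal", "litter")])
  as_herd_records(df, ped)
}

#' Write phenotype records to file
#' @param rec an `sge_records` data frame (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(rec, path) {
  cols <- c("animal", "sex", "birth_ym", "group", "group_size", "litter",
            "age", "adg", "farrow_ym", "stay", "nba1")
  utils::write.table(rec[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-tabulate trait recording overlap
#'
#' @param rec an `sge_records` data frame.
#' @return 3 x 3 matrix: diagonal = records per trait, off-diagonal =
#'   animals with both traits recorded.
#' @export
cross_tabulate_traits <- function(rec) {
  obs <- cbind(ADG = !is.na(rec$adg), STAY = !is.na(rec$stay),
               NBA1 = !is.na(rec$nba1))
  crossprod(obs * 1L)
}

#' Dilution weight for a social group
#'
#' `(n_bar - 1) / (n_g - 1)`: scales social contributions so that the summed
#' social load of every record equals `n_bar - 1` regardless of pen size.
#'
#' @param n_g group size(s), each at least 2.
#' @param n_bar average group size.
#' @return Numeric dilution weight(s).
#' @export
dilution_factor <- function(n_g, n_bar) {
  if (any(n_g < 2)) stop("social model undefined for groups of size < 2")
  (n_bar - 1) / (n_g - 1)
}

#' Pen (group) structure with dilution weights
#'
#' @param rec an `sge_records` data frame.
#' @param n_bar average group size used for dilution (default 8.2).
#' @return An `sge_groups` list: group ids, member row indices (into `rec`),
#'   sizes and dilution weights.
#' @export
build_groups <- function(rec, n_bar = 8.2) {
  rows <- which(!is.na(rec$adg))
  members <- split(rows, rec$group[rows])
  size <- lengths(members)
  if (any(size < 2))
    stop("group(s) of size 1 (social model undefined): ",
         paste(names(members)[size < 2], collapse = ", "))
  structure(list(id = names(members), members = members,
                 size = as.integer(size),
                 dilution = dilution_factor(size, n_bar),
                 n_bar = n_bar),
            class = "sge_groups")
}

#' Social genetic incidence rows (Z_S)
#'
#' Row i (an ADG record) carries the dilution weight of its pen at the
#' social-effect column of every pen mate, and zero at the record's own
#' animal; each row sums to `n_bar - 1` by construction.
#'
#' @param rec an `sge_records` data frame.
#' @param groups an `sge_groups` structure.
#' @return Sparse matrix, rows = ADG records (in `rec` row order of observed
#'   ADG), columns = pedigree animals.
#' @export
build_social_incidence <- function(rec, groups) {
  rows <- which(!is.na(rec$adg))
  rowpos <- match(rows, rows)
  n_anim <- max(rec$code)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (g in seq_along(groups$members)) {
    mem <- groups$members[[g]]
    d <- groups$dilution[[g]]
    codes <- rec$code[mem]
    pos <- match(mem, rows)
    for (a in seq_along(mem)) {
      mates <- codes[-a]
      ti <- c(ti, rep(pos[a], length(mates)))
      tj <- c(tj, mates)
      tx <- c(tx, rep(d, length(mates)))
    }
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(length(rows), n_anim))
}

#' Social early-life (mate birth litter) incidence rows (Q)
#'
#' Row i carries `dilution * m_L` at the column of litter L, where `m_L`
#' is the number of pen mates of i born in litter L. Mates from the
#' record's own birth litter count unless `own_litter = FALSE`.
#'
#' @param rec an `sge_records` data frame.
#' @param groups an `sge_groups` structure.
#' @param own_litter include pen mates from the record's own birth litter
#'   (default `TRUE`).
#' @return Sparse matrix, rows = ADG records, columns = litter levels.
#' @export
build_social_litter_incidence <- function(rec, groups, own_litter = TRUE) {
  rows <- which(!is.na(rec$adg))
  if (anyNA(rec$litter_code[rows]))
    stop("grouped animal(s) without a birth litter id")
  n_lit <- length(attr(rec, "litter_levels"))
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (g in seq_along(groups$members)) {
    mem <- groups$members[[g]]
    d <- groups$dilution[[g]]
    lits <- rec$litter_code[mem]
    pos <- match(mem, rows)
    for (a in seq_along(mem)) {
      ml <- lits[-a]
      if (!own_litter) ml <- ml[ml != lits[a]]
      if (!length(ml)) next
      tab <- table(ml)
      ti <- c(ti, rep(pos[a], length(tab)))
      tj <- c(tj, as.integer(names(tab)))
      tx <- c(tx, d * as.numeric(tab))
    }
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(length(rows), n_lit))
}

one_hot <- function(values) {
  lev <- unique(values)
  M <- Matrix::sparseMatrix(i = seq_along(values), j = match(values, lev),
                            x = 1, dims = c(length(values), length(lev)))
  list(M = M, levels = as.character(lev))
}

#' Group-size fixed-effect class
#'
#' Default binning: sizes 4..14 map to singleton classes (11 levels);
#' out-of-range sizes are clamped to the nearest bound.
#'
#' @param size integer group sizes.
#' @param range inclusive class range (default `c(4, 14)`).
#' @return Integer class labels.
#' @export
bin_group_size <- function(size, range = c(4L, 14L)) {
  pmin(pmax(as.integer(size), range[1L]), range[2L])
}

#' Fixed-effect design columns for one trait
#'
#' Growth (ADG): one-hot birth year-month, sex and group-size class, plus
#' age and age-squared covariates centred at their means. Sow traits
#' (STAY, NBA1): one-hot farrowing year-month. Levels are assigned in
#' first-appearance order; only levels observed for the trait get columns.
#' A constant covariate column (zero after centring) is flagged with a
#' warning.
#'
#' @param rec an `sge_records` data frame.
#' @param trait `"ADG"`, `"STAY"` or `"NBA1"`.
#' @return List: sparse design matrix `X` (rows = records with the trait
#'   observed), column labels, and the covariate centres used.
#' @export
encode_fixed_effects <- function(rec, trait = c("ADG", "STAY", "NBA1")) {
  trait <- match.arg(trait)
  if (trait == "ADG") {
    rows <- which(!is.na(rec$adg))
    ym <- one_hot(rec$birth_ym[rows])
    sx <- one_hot(rec$sex[rows])
    gs <- one_hot(bin_group_size(rec$group_size[rows]))
    age <- rec$age[rows]
    age_c <- age - mean(age)
    age2_c <- age^2 - mean(age^2)
    if (all(age_c == 0)) warning("age covariate is constant; column is all zero after centring")
    X <- cbind(ym$M, sx$M, gs$M,
               Matrix::Matrix(cbind(age_c, age2_c), sparse = TRUE))
    labels <- c(paste0("birth_ym:", ym$levels), paste0("sex:", sx$levels),
                paste0("group_size:", gs$levels), "age", "age2")
    centres <- c(age = mean(age), age2 = mean(age^2))
  } else {
    col <- if (trait == "STAY") rec$stay else rec$nba1
    rows <- which(!is.na(col))
    ym <- one_hot(rec$farrow_ym[rows])
    X <- ym$M
    labels <- paste0("farrow_ym:", ym$levels)
    centres <- numeric(0)
  }
  list(X = methods::as(X, "CsparseMatrix"), labels = labels, rows = rows,
       centres = centres)
}

#' Assemble the multi-trait equation system
#'
#' Stacks the growth model (fixed effects, direct and dilution-weighted
#' social genetic effects, pen group, own birth litter, mates' birth
#' litters) and the sow models (fixed effects, direct genetic effect, own
#' birth litter) into one sparse design over a single unknown vector:
#' three trait-wise fixed blocks, a genetic block of 4 correlated effects
#' for every pedigree animal (parents without records included), one group
#' effect per pen, and a litter block of 4 correlated effects per birth
#' litter (growth and sow litters share the level set).
#'
#' @param rec an `sge_records` data frame.
#' @param groups an `sge_groups` structure (see [build_groups()]).
#' @param ped the `sge_pedigree`.
#' @param n_bar average group size for dilution and total breeding values
#'   (default `groups$n_bar`).
#' @param own_litter_social pen mates from the record's own birth litter
#'   contribute to its social early-life row (default `TRUE`).
#' @param with_inbreeding build A-inverse with inbreeding adjustment.
#' @return An `sge_system` list: sparse design `W`, data vector `y`, data
#'   row trait indices, stayability rows/categories, column block layout,
#'   per-column prior descriptors, and the sparse A-inverse.
#' @export
assemble_system <- function(rec, groups, ped, n_bar = NULL,
                            own_litter_social = TRUE, with_inbreeding = TRUE) {
  if (is.null(n_bar)) n_bar <- groups$n_bar
  if (!isTRUE(all.equal(n_bar, groups$n_bar)))
    stop("n_bar differs from the dilution used to build the group structure")
  n_anim <- n_animals(ped)
  n_lit <- length(attr(rec, "litter_levels"))
  n_grp <- length(groups$id)

  fx <- lapply(c("ADG", "STAY", "NBA1"), function(t) encode_fixed_effects(rec, t))
  names(fx) <- c("ADG", "STAY", "NBA1")
  adg_rows <- fx$ADG$rows; stay_rows <- fx$STAY$rows; nba_rows <- fx$NBA1$rows
  n_adg <- length(adg_rows); n_stay <- length(stay_rows); n_nba <- length(nba_rows)

  widths <- c(fixed_ADG = ncol(fx$ADG$X), fixed_STAY = ncol(fx$STAY$X),
              fixed_NBA1 = ncol(fx$NBA1$X), genetic = 4L * n_anim,
              group = n_grp, litter = 4L * n_lit)
  offs <- cumsum(c(0L, widths))[seq_along(widths)]
  names(offs) <- names(widths)

  gen_col <- function(code, eff) offs[["genetic"]] + 4L * (code - 1L) + eff
  lit_col <- function(lc, eff) offs[["litter"]] + 4L * (lc - 1L) + eff

  # data rows: ADG block, then STAY (liability), then NBA1
  n_data <- n_adg + n_stay + n_nba
  data_trait <- rep(1:3, c(n_adg, n_stay, n_nba))
  y <- c(rec$adg[adg_rows], rep(0, n_stay), rec$nba1[nba_rows])

  tri <- function(M, row_offset, col_offset) {
    T <- methods::as(methods::as(M, "CsparseMatrix"), "TsparseMatrix")
    list(i = T@i + 1L + row_offset, j = T@j + 1L + col_offset, x = T@x)
  }
  parts <- list()
  parts$fx_adg <- tri(fx$ADG$X, 0L, offs[["fixed_ADG"]])
  parts$fx_stay <- tri(fx$STAY$X, n_adg, offs[["fixed_STAY"]])
  parts$fx_nba <- tri(fx$NBA1$X, n_adg + n_stay, offs[["fixed_NBA1"]])
  # direct genetic effects
  parts$zd_adg <- list(i = seq_len(n_adg), j = gen_col(rec$code[adg_rows], 1L),
                       x = rep(1, n_adg))
  parts$zd_stay <- list(i = n_adg + seq_len(n_stay),
                        j = gen_col(rec$code[stay_rows], 3L), x = rep(1, n_stay))
  parts$zd_nba <- list(i = n_adg + n_stay + seq_len(n_nba),
                       j = gen_col(rec$code[nba_rows], 4L), x = rep(1, n_nba))
  # social genetic effects of pen mates (dilution-weighted)
  ZS <- build_social_incidence(rec, groups)
  TS <- methods::as(ZS, "TsparseMatrix")
  parts$zs <- list(i = TS@i + 1L, j = gen_col(TS@j + 1L, 2L), x = TS@x)
  # pen group
  grp_of_row <- match(rec$group[adg_rows], groups$id)
  parts$v <- list(i = seq_len(n_adg), j = offs[["group"]] + grp_of_row,
                  x = rep(1, n_adg))
  # own birth litter
  parts$u_adg <- list(i = seq_len(n_adg),
                      j = lit_col(rec$litter_code[adg_rows], 1L),
                      x = rep(1, n_adg))
  parts$u_stay <- list(i = n_adg + seq_len(n_stay),
                       j = lit_col(rec$litter_code[stay_rows], 3L),
                       x = rep(1, n_stay))
  parts$u_nba <- list(i = n_adg + n_stay + seq_len(n_nba),
                      j = lit_col(rec$litter_code[nba_rows], 4L),
                      x = rep(1, n_nba))
  # mates' birth litters (social early-life environment)
  Q <- build_social_litter_incidence(rec, groups, own_litter = own_litter_social)
  TQ <- methods::as(Q, "TsparseMatrix")
  parts$q <- list(i = TQ@i + 1L, j = lit_col(TQ@j + 1L, 2L), x = TQ@x)

  W <- Matrix::sparseMatrix(
    i = unlist(lapply(parts, `[[`, "i")),
    j = unlist(lapply(parts, `[[`, "j")),
    x = unlist(lapply(parts, `[[`, "x")),
    dims = c(n_data, sum(widths)))

  n_total <- sum(widths)
  col_type <- integer(n_total) # 0 fixed, 1 genetic, 2 group, 3 litter
  col_unit <- integer(n_total)
  col_effect <- integer(n_total)
  gidx <- offs[["genetic"]] + seq_len(4L * n_anim)
  col_type[gidx] <- 1L
  col_unit[gidx] <- rep(seq_len(n_anim), each = 4L)
  col_effect[gidx] <- rep(1:4, n_anim)
  vidx <- offs[["group"]] + seq_len(n_grp)
  col_type[vidx] <- 2L
  col_unit[vidx] <- seq_len(n_grp)
  lidx <- offs[["litter"]] + seq_len(4L * n_lit)
  col_type[lidx] <- 3L
  col_unit[lidx] <- rep(seq_len(n_lit), each = 4L)
  col_effect[lidx] <- rep(1:4, n_lit)

  structure(list(
    W = methods::as(W, "CsparseMatrix"), y = y, data_trait = data_trait,
    stay_data_rows = n_adg + seq_len(n_stay),
    stay_cat = as.integer(rec$stay[stay_rows]),
    col_type = col_type, col_unit = col_unit, col_effect = col_effect,
    offsets = offs, widths = widths,
    n_animals = n_anim, n_groups = n_grp, n_litters = n_lit,
    n_records = c(ADG = n_adg, STAY = n_stay, NBA1 = n_nba),
    Ainv = build_A_inverse(ped, with_inbreeding = with_inbreeding),
    n_bar = n_bar,
    fixed_labels = lapply(fx, `[[`, "labels"),
    animal_labels = ped$labels,
    group_labels = groups$id,
    litter_labels = attr(rec, "litter_levels")),
    class = "sge_system")
}

#' @exportS3Method base::print
print.sge_system <- function(x, ...) {
  cat("<sge_system> ", length(x$y), " data rows (",
      paste(names(x$n_records), x$n_records, collapse = ", "), "), ",
      ncol(x$W), " unknowns\n", sep = "")
  cat("  blocks:", paste(names(x$widths), x$widths, collapse = ", "), "\n")
  invisible(x)
}
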