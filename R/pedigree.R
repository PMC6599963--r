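# Pedigree handling: validation, topological ordering, the numerator
# relationship matrix A (dense, small pedigrees only) and its sparse inverse
# built directly from pedigree rules with optional inbreeding adjustment.

new_pedigree <- function(labels, sire, dam, sorted = NA) {
  stopifnot(length(labels) == length(sire), length(sire) == length(dam))
  ped <- structure(
    list(labels = as.character(labels),
         sire = as.integer(sire),
         dam = as.integer(dam)),
    class = "sge_pedigree")
  ped$sorted <- if (is.na(sorted)) is_sorted(ped) else sorted
  ped
}

#' Number of animals in a pedigree
#' @param ped an `sge_pedigree` object.
#' @return Integer count of animals (founders and phantom parents included).
#' @export
n_animals <- function(ped) length(ped$labels)

is_sorted <- function(ped) {
  idx <- seq_along(ped$labels)
  all(ped$sire < idx) && all(ped$dam < idx)
}

#' Build a pedigree from a data frame
#'
#' The first three columns are taken as animal, sire and dam labels. Unknown
#' parents are encoded as `0`, the empty string or `NA`. Parents that are
#' referenced but have no row of their own ("phantom" parents) are appended
#' as founders, then the pedigree is topologically sorted so that every
#' parent precedes its offspring.
#'
#' @param df data frame with at least three columns (animal, sire, dam).
#' @return An `sge_pedigree`: animal labels plus integer sire/dam codes
#'   (0 = unknown), ordered parents-before-offspring.
#' @export
as_pedigree <- function(df) {
  if (ncol(df) < 3L) stop("pedigree table needs at least 3 columns (animal, sire, dam)")
  an <- trimws(as.character(df[[1L]]))
  si <- trimws(as.character(df[[2L]]))
  da <- trimws(as.character(df[[3L]]))
  unk <- function(x) is.na(x) | x == "0" | x == ""
  si[unk(si)] <- NA_character_
  da[unk(da)] <- NA_character_
  if (any(unk(an))) stop("missing animal id in pedigree row(s): ",
                         paste(which(unk(an)), collapse = ", "))
  dup <- an[duplicated(an)]
  if (length(dup))
    stop("duplicate animal id(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  phantom <- setdiff(c(si, da), c(an, NA_character_))
  labels <- c(an, phantom)
  code <- function(x) {
    i <- match(x, labels)
    i[is.na(i)] <- 0L
    i
  }
  sire <- c(code(si), integer(length(phantom)))
  dam <- c(code(da), integer(length(phantom)))
  topological_sort(new_pedigree(labels, sire, dam))
}

#' Read a pedigree file
#'
#' Whitespace- or tab-delimited text with three or more columns
#' (animal, sire, dam); a header line is detected automatically. Unknown
#' parents are `0` or empty.
#'
#' @param path path to the pedigree file.
#' @return An `sge_pedigree` (see [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[\t ,;]+")[[1L]]
  header <- any(tolower(first) %in% c("animal", "id", "sire", "dam", "sir", "mother", "father"))
  df <- utils::read.table(path, header = header, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  as_pedigree(df)
}

#' Write a sorted, recoded pedigree
#'
#' Emits the pedigree in parents-before-offspring order with original labels,
#' plus a companion `<path>.map` file listing the internal integer code of
#' each label.
#'
#' @param ped an `sge_pedigree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  lab <- function(code) ifelse(code == 0L, "0", ped$labels[pmax(code, 1L)])
  df <- data.frame(animal = ped$labels, sire = lab(ped$sire), dam = lab(ped$dam))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(code = seq_along(ped$labels), label = ped$labels)
  utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @exportS3Method base::print
print.sge_pedigree <- function(x, ...) {
  cat("<sge_pedigree> ", n_animals(x), " animals, ",
      sum(x$sire == 0L & x$dam == 0L), " founders, sorted = ", x$sorted,
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sge_pedigree <- function(x, ...) {
  lab <- function(code) ifelse(code == 0L, NA_character_, x$labels[pmax(code, 1L)])
  data.frame(animal = x$labels, sire = lab(x$sire), dam = lab(x$dam),
             stringsAsFactors = FALSE)
}

find_cycle <- function(ped, unplaced) {
  # follow parent links among unplaced animals until one repeats
  start <- which(unplaced)[1L]
  chain <- integer(0)
  cur <- start
  repeat {
    if (cur %in% chain) {
      chain <- c(chain[which(chain == cur):length(chain)], cur)
      return(ped$labels[chain])
    }
    chain <- c(chain, cur)
    nxt <- c(ped$sire[cur], ped$dam[cur])
    nxt <- nxt[nxt != 0L & unplaced[pmax(nxt, 1L)]]
    if (!length(nxt)) return(ped$labels[chain]) # dead end; report chain anyway
    cur <- nxt[1L]
  }
}

#' Order a pedigree parents-before-offspring
#'
#' A pedigree that already satisfies the ordering is returned unchanged.
#' Otherwise animals are re-ordered generation-wise (founders first), keeping
#' the original relative order within each wave. Cyclic pedigrees (an animal
#' that is its own ancestor) are a fatal error reporting the offending chain.
#'
#' @param ped an `sge_pedigree`.
#' @return The sorted `sge_pedigree`; original labels are preserved.
#' @export
topological_sort <- function(ped) {
  n <- n_animals(ped)
  if (is_sorted(ped)) {
    ped$sorted <- TRUE
    return(ped)
  }
  placed <- logical(n)
  ord <- integer(n)
  k <- 0L
  while (k < n) {
    par_ok <- function(p) p == 0L | placed[pmax(p, 1L)]
    ready <- which(!placed & par_ok(ped$sire) & par_ok(ped$dam))
    if (!length(ready)) {
      chain <- find_cycle(ped, !placed)
      stop("pedigree cycle detected: ", paste(chain, collapse = " -> "))
    }
    ord[(k + 1L):(k + length(ready))] <- ready
    placed[ready] <- TRUE
    k <- k + length(ready)
  }
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  recode <- function(p) ifelse(p == 0L, 0L, pos[pmax(p, 1L)])
  new_pedigree(ped$labels[ord], recode(ped$sire)[ord], recode(ped$dam)[ord],
               sorted = TRUE)
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Recursive (tabular) construction of the additive relationship matrix A:
#' `A[i,i] = 1 + F_i` with `F_i = 0.5 * A[s,d]`, and
#' `A[j,i] = 0.5 * (A[j,s] + A[j,d])` for `j < i`. Intended as the exact
#' oracle for small pedigrees; memory is O(N^2).
#'
#' @param ped a sorted `sge_pedigree`.
#' @return Dense symmetric N x N matrix with animal labels as dimnames.
#' @export
tabular_A <- function(ped) {
  if (!ped$sorted) stop("pedigree must be sorted parents-before-offspring; run topological_sort()")
  n <- n_animals(ped)
  A <- matrix(0, n, n, dimnames = list(ped$labels, ped$labels))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
  }
  A
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' Sequential computation of inbreeding coefficients without forming A:
#' for each animal with both parents known, its diagonal `A[i,i]` is
#' accumulated from the Mendelian-sampling variances of its ancestors.
#'
#' @param ped a sorted `sge_pedigree`.
#' @return Numeric vector of F coefficients, one per animal.
#' @export
inbreeding <- function(ped) {
  if (!ped$sorted) stop("pedigree must be sorted parents-before-offspring")
  n <- n_animals(ped)
  F <- numeric(n)
  D <- numeric(n) # Mendelian-sampling variance of each animal
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    D[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (F[s] + F[d])
            else if (s > 0L) 0.75 - 0.25 * F[s]
            else if (d > 0L) 0.75 - 0.25 * F[d]
            else 1
    if (s > 0L && d > 0L) {
      L <- numeric(i)
      L[i] <- 1
      acc <- 0
      for (j in i:1) {
        lj <- L[j]
        if (lj != 0) {
          sj <- ped$sire[j]; dj <- ped$dam[j]
          if (sj > 0L) L[sj] <- L[sj] + 0.5 * lj
          if (dj > 0L) L[dj] <- L[dj] + 0.5 * lj
          acc <- acc + lj * lj * D[j]
        }
      }
      F[i] <- acc - 1
    }
  }
  names(F) <- ped$labels
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from per-animal pedigree contributions:
#' each animal adds `alpha * {(i,i): 1, (i,parent): -1/2, (parent,parent'): 1/4}`
#' with `alpha = 1 / (1 - 0.25 * sum_p (1 + F_p))` over its known parents.
#' With `with_inbreeding = FALSE` all F are taken as zero, giving the classic
#' coefficients 2 (both parents known), 4/3 (one known) and 1 (none known).
#'
#' @param ped a sorted `sge_pedigree`.
#' @param with_inbreeding logical; adjust Mendelian-sampling variances for
#'   parental inbreeding (default `TRUE`).
#' @return Sparse symmetric `dgCMatrix` (both triangles stored).
#' @export
build_A_inverse <- function(ped, with_inbreeding = TRUE) {
  if (!ped$sorted) stop("pedigree must be sorted parents-before-offspring")
  n <- n_animals(ped)
  F <- if (with_inbreeding) inbreeding(ped) else numeric(n)
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], NA_real_)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], NA_real_)
  dvar <- 1 - 0.25 * (ifelse(s > 0L, 1 + Fs, 0) + ifelse(d > 0L, 1 + Fd, 0))
  alpha <- 1 / dvar
  i_idx <- seq_len(n)
  ti <- c(i_idx); tj <- c(i_idx); tx <- c(alpha)
  ks <- which(s > 0L); kd <- which(d > 0L); kb <- which(s > 0L & d > 0L)
  add <- function(ii, jj, xx) {
    ti <<- c(ti, ii, jj); tj <<- c(tj, jj, ii); tx <<- c(tx, xx, xx)
  }
  if (length(ks)) {
    add(ks, s[ks], -alpha[ks] / 2)
    ti <- c(ti, s[ks]); tj <- c(tj, s[ks]); tx <- c(tx, alpha[ks] / 4)
  }
  if (length(kd)) {
    add(kd, d[kd], -alpha[kd] / 2)
    ti <- c(ti, d[kd]); tj <- c(tj, d[kd]); tx <- c(tx, alpha[kd] / 4)
  }
  if (length(kb)) {
    ti <- c(ti, s[kb], d[kb]); tj <- c(tj, d[kb], s[kb])
    tx <- c(tx, alpha[kb] / 4, alpha[kb] / 4)
  }
  Ai <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                             dimnames = list(ped$labels, ped$labels))
  methods::as(Ai, "generalMatrix")
}
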