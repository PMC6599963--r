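# Fixtures built in code: small pedigrees, simulated herds and a
# hand-assembled single-column system for conjugate checks.

trio_df <- function() {
  data.frame(animal = c("s", "d", "o"), sire = c("0", "0", "s"),
             dam = c("0", "0", "d"), stringsAsFactors = FALSE)
}

# full sibs a, b (parents s x d) mated to produce x: F_x = 0.25
fullsib_mating_df <- function() {
  data.frame(animal = c("s", "d", "a", "b", "x"),
             sire = c("0", "0", "s", "s", "a"),
             dam = c("0", "0", "d", "d", "b"),
             stringsAsFactors = FALSE)
}

tiny_herd <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache)) cache <<- simulate_herd(herd_scenario("tiny"), seed = seed)
    cache
  }
})

tiny_system <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    herd <- tiny_herd()
    rec <- as_herd_records(herd$records, herd$ped)
    groups <- build_groups(rec, n_bar = 8.2)
    cache <<- list(herd = herd, rec = rec, groups = groups,
                   system = assemble_system(rec, groups, herd$ped))
    cache
  }
})

# a system with a single intercept column and iid residuals, for conjugate
# closed-form checks of the location sweep
intercept_system <- function(y) {
  n <- length(y)
  W <- methods::as(Matrix::Matrix(rep(1, n), ncol = 1, sparse = TRUE),
                   "CsparseMatrix")
  dummyA <- methods::as(Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                             dims = c(1, 1)), "generalMatrix")
  structure(list(
    W = W, y = y, data_trait = rep(1L, n),
    stay_data_rows = integer(0), stay_cat = integer(0),
    col_type = 0L, col_unit = 0L, col_effect = 0L,
    offsets = c(fixed_ADG = 0L, genetic = 1L, group = 1L, litter = 1L),
    widths = c(fixed_ADG = 1L),
    n_animals = 0L, n_groups = 0L, n_litters = 0L,
    n_records = c(ADG = n, STAY = 0L, NBA1 = 0L),
    Ainv = dummyA, n_bar = 8.2), class = "sge_system")
}

# variance state with unit residuals and irrelevant covariance blocks
unit_varstate <- function(sigma2_e_adg = 1) {
  list(C = diag(4), K = diag(4), sigma2_g = 1,
       sigma2_e = c(ADG = sigma2_e_adg, STAY = 1, NBA1 = 1))
}

# brute-force HPD oracle: scan every window of ceil(mass*m) sorted samples
brute_hpd <- function(x, mass = 0.95) {
  xs <- sort(x)
  m <- length(xs)
  w <- ceiling(mass * m)
  best <- c(xs[1L], xs[w]); bw <- xs[w] - xs[1L]
  for (i in seq_len(m - w + 1L)) {
    width <- xs[i + w - 1L] - xs[i]
    if (width < bw - 1e-15) { bw <- width; best <- c(xs[i], xs[i + w - 1L]) }
  }
  best
}

random_pd4 <- function() {
  M <- matrix(rnorm(16), 4)
  crossprod(M) + diag(4) * 0.1
}
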