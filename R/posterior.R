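# Post-Gibbs analysis: highest-posterior-density intervals, batch-means
# Monte Carlo error, and chain summaries including per-sample derived
# genetic parameters.

#' Highest posterior density interval
#'
#' Shortest contiguous window of sorted samples containing at least
#' `mass` of the draws. Ties are broken by the lowest-starting window.
#'
#' @param samples numeric vector of posterior draws (>= 20).
#' @param mass probability mass of the interval (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  m <- length(samples)
  w <- ceiling(mass * m)
  if (m < 20L || w > m) stop("too few samples (", m, ") for a ", mass, " HPD interval")
  xs <- sort(samples)
  starts <- seq_len(m - w + 1L)
  widths <- xs[starts + w - 1L] - xs[starts]
  i <- which.min(widths) # which.min takes the first minimum: lowest start
  c(lower = xs[i], upper = xs[i + w - 1L])
}

#' Batch-means Monte Carlo standard error
#'
#' Splits the chain into `n_batches` consecutive batches (discarding the
#' remainder) and reports the standard deviation of batch means divided by
#' `sqrt(n_batches)`. Autocorrelation inflates batch-mean spread, so this
#' is a serial-correlation-aware standard error of the posterior mean.
#'
#' @param samples numeric vector of draws; needs at least `2 * n_batches`.
#' @param n_batches number of batches (default 20).
#' @return Scalar Monte Carlo standard error.
#' @export
mc_error <- function(samples, n_batches = 20L) {
  m <- length(samples)
  if (m < 2L * n_batches) stop("need at least ", 2L * n_batches, " samples, got ", m)
  b <- m %/% n_batches
  use <- samples[seq_len(b * n_batches)]
  bm <- colMeans(matrix(use, nrow = b))
  stats::sd(bm) / sqrt(n_batches)
}

#' Effective-sample-size-based Monte Carlo error
#'
#' Alternative to [mc_error()]: `sd(x) / sqrt(ESS)` with the effective
#' sample size from the initial-positive-sequence estimate of the
#' autocorrelation time.
#'
#' @inheritParams mc_error
#' @return Scalar Monte Carlo standard error.
#' @export
mc_error_ess <- function(samples) {
  m <- length(samples)
  if (m < 40L) stop("need at least 40 samples, got ", m)
  if (stats::sd(samples) == 0) return(0)
  ac <- stats::acf(samples, lag.max = min(m - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1L] - 1L)]
  ess <- m / (1 + 2 * sum(ac))
  stats::sd(samples) / sqrt(max(ess, 1))
}

#' Construct a chain object from a sample matrix
#'
#' @param samples numeric matrix, one stored draw per row, named columns.
#' @param n_bar average group size associated with the fit.
#' @param config optional list of chain settings (iterations, burn-in,
#'   thinning, seed).
#' @return An `sge_chain` object.
#' @export
new_chain <- function(samples, n_bar = 8.2, config = list()) {
  stopifnot(is.matrix(samples), !is.null(colnames(samples)))
  structure(list(samples = samples, n_bar = n_bar, config = config),
            class = "sge_chain")
}

#' @exportS3Method base::print
print.sge_chain <- function(x, ...) {
  cat("<sge_chain> ", nrow(x$samples), " stored samples x ",
      ncol(x$samples), " parameters (n_bar = ", x$n_bar, ")\n", sep = "")
  invisible(x)
}

#' Per-sample derived-parameter series for a chain
#'
#' Reconstructs the variance state of every stored draw and applies
#' [derived_params()], so that ratios and correlations are averaged on the
#' correct (per-sample) scale.
#'
#' @param chain an `sge_chain` from [run_gibbs()] or [new_chain()].
#' @return Numeric matrix, one row per stored sample.
#' @export
derived_series <- function(chain) {
  s <- chain$samples
  out <- NULL
  for (i in seq_len(nrow(s))) {
    vs <- varstate_from_row(s[i, ])
    d <- derived_params(vs, chain$n_bar)
    if (is.null(out)) out <- matrix(NA_real_, nrow(s), length(d),
                                    dimnames = list(NULL, names(d)))
    out[i, ] <- d
  }
  out
}

# rebuild (C, K, sigma2_g, sigma2_e) from a stored flat sample row
varstate_from_row <- function(row) {
  C <- matrix(0, 4, 4, dimnames = list(GEN_EFFECTS, GEN_EFFECTS))
  K <- matrix(0, 4, 4, dimnames = list(LIT_EFFECTS, LIT_EFFECTS))
  ut <- upper.tri(C, diag = TRUE)
  C[ut] <- row[paste0("C_", which(ut))]
  C <- C + t(C) - diag(diag(C))
  K[ut] <- row[paste0("K_", which(ut))]
  K <- K + t(K) - diag(diag(K))
  list(C = C, K = K, sigma2_g = row[["s2_g"]],
       sigma2_e = c(ADG = row[["s2_e_ADG"]], STAY = row[["s2_e_STAY"]],
                    NBA1 = row[["s2_e_NBA1"]]))
}

# flatten a variance state into the stored-sample layout
varstate_to_row <- function(vs) {
  ut <- upper.tri(vs$C, diag = TRUE)
  out <- c(vs$C[ut], vs$K[ut], vs$sigma2_g, vs$sigma2_e)
  names(out) <- c(paste0("C_", which(ut)), paste0("K_", which(ut)),
                  "s2_g", "s2_e_ADG", "s2_e_STAY", "s2_e_NBA1")
  out
}

# human-readable labels for the flat layout
sample_param_labels <- function() {
  ut <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  gen <- ifelse(ut[, "row"] == ut[, "col"],
                paste0("s2_", GEN_EFFECTS[ut[, "row"]]),
                paste0("cov_", GEN_EFFECTS[ut[, "row"]], "_", GEN_EFFECTS[ut[, "col"]]))
  lit <- ifelse(ut[, "row"] == ut[, "col"],
                paste0("s2_", LIT_EFFECTS[ut[, "row"]]),
                paste0("cov_", LIT_EFFECTS[ut[, "row"]], "_", LIT_EFFECTS[ut[, "col"]]))
  ks <- which(upper.tri(diag(4), diag = TRUE))
  stats::setNames(c(gen, lit, "s2_group", "s2_e_ADG", "s2_e_STAY", "s2_e_NBA1"),
                  c(paste0("C_", ks), paste0("K_", ks),
                    "s2_g", "s2_e_ADG", "s2_e_STAY", "s2_e_NBA1"))
}

#' Summarise a Gibbs chain
#'
#' Posterior mean, SD, 95% highest-posterior-density interval, batch-means
#' Monte Carlo error and an HPD-excludes-zero significance flag for every
#' stored variance/covariance series and (optionally) every derived series
#' computed per sample.
#'
#' @param chain an `sge_chain`.
#' @param derived also summarise per-sample derived parameters
#'   (default `TRUE`).
#' @param mass HPD mass (default 0.95).
#' @return Data frame with one row per parameter.
#' @export
summarize_chain <- function(chain, derived = TRUE, mass = 0.95) {
  s <- chain$samples
  labels <- sample_param_labels()
  colnames(s) <- ifelse(colnames(s) %in% names(labels),
                        labels[colnames(s)], colnames(s))
  if (derived) s <- cbind(s, derived_series(chain))
  summ <- lapply(colnames(s), function(p) {
    x <- s[, p]
    h <- hpd_interval(x, mass)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               mc_error = mc_error(x),
               significant = h[["lower"]] > 0 | h[["upper"]] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  out
}

#' Export a chain as flat text
#'
#' Long-format tab-separated text (`sample`, `parameter`, `value`), one row
#' per stored draw and parameter, for interoperability with external
#' post-Gibbs tooling.
#'
#' @param chain an `sge_chain`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  s <- chain$samples
  long <- data.frame(sample = rep(seq_len(nrow(s)), times = ncol(s)),
                     parameter = rep(colnames(s), each = nrow(s)),
                     value = as.vector(s))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat-text chain export
#'
#' @param path file written by [write_chain()].
#' @param n_bar average group size to attach to the chain.
#' @return An `sge_chain`.
#' @export
read_chain <- function(path, n_bar = 8.2) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  pars <- unique(long$parameter)
  m <- max(long$sample)
  s <- matrix(NA_real_, m, length(pars), dimnames = list(NULL, pars))
  for (p in pars) s[, p] <- long$value[long$parameter == p]
  new_chain(s, n_bar = n_bar)
}
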