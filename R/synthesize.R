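#' Draw a per-gene parameter grid
#'
#' Independent log-uniform draws of \code{k_on} and \code{k_off} inside the
#' given ranges with \code{s} fixed (the sampling scheme used to map the
#' identifiability landscape: switching rates uniform in log space, fixed
#' transcription rate).
#'
#' @param n_genes number of genes.
#' @param kon_range,koff_range positive 2-vectors (log-uniform bounds).
#' @param s transcription rate, fixed across genes (default 100), or a
#'   2-vector for log-uniform sampling of \code{s} too.
#' @param seed optional integer seed.
#' @return a \code{\link{kinetic_params}} table.
#' @export
sample_parameter_grid <- function(n_genes, kon_range = c(0.01, 100),
                                  koff_range = c(0.01, 100), s = 100,
                                  seed = NULL) {
  stopifnot(all(kon_range > 0), all(koff_range > 0), all(s > 0))
  with_seed(seed, {
    logu <- function(rg) exp(stats::runif(n_genes, log(min(rg)), log(max(rg))))
    kinetic_params(k_on = logu(kon_range), k_off = logu(koff_range),
                   s = if (length(s) == 2) logu(s) else rep(s, n_genes))
  })
}

#' Simulate a count matrix from the generative model
#'
#' For each gene i and cell j draws \code{p_ij ~ Beta(k_on_i, k_off_i)} and
#' \code{x_ij ~ Poisson(t_i t_j s_i p_ij)}, independently. With unit
#' offsets this reduces to i.i.d. Poisson-beta counts per gene.
#'
#' @param params a \code{\link{kinetic_params}} table.
#' @param n_cells number of cells.
#' @param gene_lengths optional transcript lengths (bp); the model offsets
#'   \code{t_i} are then lengths scaled by their median, as in
#'   \code{\link{length_offsets}}.
#' @param norm_factors optional per-cell factors \code{t_j} (default 1).
#' @param seed optional integer seed.
#' @return a \code{\link{count_matrix}} carrying the supplied lengths and
#'   factors.
#' @export
simulate_dataset <- function(params, n_cells, gene_lengths = NULL,
                             norm_factors = NULL, seed = NULL) {
  stopifnot(n_cells >= 1)
  G <- nrow(params)
  ti <- if (is.null(gene_lengths)) rep(1, G)
        else gene_lengths / stats::median(gene_lengths)
  tj <- norm_factors %||% rep(1, n_cells)
  stopifnot(length(tj) == n_cells)
  x <- with_seed(seed, {
    p <- matrix(stats::rbeta(G * n_cells, params$k_on, params$k_off),
                nrow = G)
    matrix(stats::rpois(G * n_cells,
                        (ti * params$s * p) * rep(tj, each = G)),
           nrow = G, dimnames = list(params$gene_id, NULL))
  })
  count_matrix(x, gene_lengths = gene_lengths, norm_factors = tj)
}

#' Parameter-recovery experiment
#'
#' Measures how well the Gibbs sampler recovers known telegraph rates as
#' the number of profiled cells grows. For each cell count a dataset is
#' simulated from \code{true_params}, the sampler run, and posterior means
#' compared with the truth by Spearman rank correlation and mean signed
#' relative error, per parameter.
#'
#' @param true_params a \code{\link{kinetic_params}} table; by default a
#'   50-gene draw from the burst-like regime typical of fitted single-cell
#'   data — activation slower than mRNA decay, inactivation faster —
#'   \code{k_on} log-uniform on [0.02, 1], \code{k_off} on [1, 10],
#'   \code{s = 100}.
#' @param cell_counts increasing integer vector of cells per experiment.
#' @param n_iter Gibbs iterations per fit (default 10000, halved burn-in).
#' @param seed optional integer seed driving all stages.
#' @param verbose print progress.
#' @return data.frame with one row per cell count: Spearman correlations
#'   \code{rho_kon}, \code{rho_koff}, \code{rho_s} and mean signed relative
#'   errors \code{bias_kon}, \code{bias_koff}, \code{bias_s}, plus the
#'   fitted estimates as an attribute \code{"fits"}.
#' @export
recovery_experiment <- function(true_params = NULL,
                                cell_counts = c(3, 6, 12, 20, 100),
                                n_iter = 10000, seed = NULL,
                                verbose = FALSE) {
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        2 * length(cell_counts) + 1)
  if (is.null(true_params))
    true_params <- sample_parameter_grid(50, kon_range = c(0.02, 1),
                                         koff_range = c(1, 10), s = 100,
                                         seed = seeds[1])
  fits <- list()
  rows <- lapply(seq_along(cell_counts), function(k) {
    nc <- cell_counts[k]
    if (verbose) message("recovery: ", nc, " cells")
    cm <- simulate_dataset(true_params, nc, seed = seeds[2 * k])
    chain <- run_gibbs(cm, n_iter = n_iter, seed = seeds[2 * k + 1])
    est <- point_estimates(chain)$estimates
    fits[[as.character(nc)]] <<- est
    rho <- function(truth, hat) {
      if (length(unique(truth)) < 2) return(NA_real_)  # e.g. s fixed at 100
      stats::cor(truth, hat, method = "spearman")
    }
    msre <- function(truth, hat) mean((hat - truth) / truth)
    data.frame(n_cells = nc,
               rho_kon = rho(true_params$k_on, est$kon_mean),
               rho_koff = rho(true_params$k_off, est$koff_mean),
               rho_s = rho(true_params$s, est$s_mean),
               bias_kon = msre(true_params$k_on, est$kon_mean),
               bias_koff = msre(true_params$k_off, est$koff_mean),
               bias_s = msre(true_params$s, est$s_mean))
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "true_params") <- true_params
  out
}
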