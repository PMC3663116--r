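#' Hyperparameters of the hierarchical model
#'
#' Gamma priors (scale parameterization, density proportional to
#' \code{v^(alpha-1) exp(-v/beta)}) on the per-gene rates. Defaults follow
#' an empirical-Bayes logic: \code{s_i} gets \code{Gamma(1, max_j x_ij)} so
#' the prior is nearly flat over the realistic range of the transcription
#' rate, and \code{k_on,i}, \code{k_off,i} get \code{Gamma(1, 100)},
#' spreading mass over the statistically identifiable switching-rate range.
#'
#' @param cm a \code{\link{count_matrix}} (used for the per-gene
#'   \code{beta_s} default).
#' @param alpha_s,beta_s shape/scale for \code{s_i}; \code{beta_s} defaults
#'   to the per-gene maximum count (recycled to one value per gene).
#' @param alpha_kon,beta_kon,alpha_koff,beta_koff shape/scale for the
#'   switching rates.
#' @return list of per-gene numeric vectors, class \code{"hyper_params"}.
#' @export
hyper_params <- function(cm, alpha_s = 1, beta_s = NULL,
                         alpha_kon = 1, beta_kon = 100,
                         alpha_koff = 1, beta_koff = 100) {
  G <- nrow(cm$counts)
  if (is.null(beta_s)) beta_s <- pmax(apply(cm$counts, 1, max), 1)
  h <- list(alpha_s = rep_len(alpha_s, G), beta_s = rep_len(beta_s, G),
            alpha_kon = rep_len(alpha_kon, G), beta_kon = rep_len(beta_kon, G),
            alpha_koff = rep_len(alpha_koff, G),
            beta_koff = rep_len(beta_koff, G))
  if (any(unlist(h) <= 0)) stop("hyperparameters must be > 0", call. = FALSE)
  class(h) <- "hyper_params"
  h
}

#' Gibbs sampler state
#'
#' @param p genes x cells matrix of auxiliary beta variables, strictly
#'   inside (0, 1).
#' @param kon,koff,s per-gene positive rate vectors.
#' @return list of class \code{"gibbs_state"}.
#' @export
gibbs_state <- function(p, kon, koff, s) {
  p <- as.matrix(p)
  if (any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  check_rates(kon, koff, s)
  structure(list(p = p, kon = kon, koff = koff, s = s),
            class = "gibbs_state")
}

#' Log posterior of the hierarchical Poisson-beta model
#'
#' The joint log density of data and parameters: the Poisson likelihood
#' with rate \code{t_i t_j s_i p_ij}, the Beta(\code{k_on,i},
#' \code{k_off,i}) density of each \code{p_ij}, and scale-parameterized
#' gamma priors on \code{s_i}, \code{k_on,i}, \code{k_off,i} (including
#' their \code{-alpha log beta - log Gamma(alpha)} normalizing terms).
#' Used to monitor convergence of the Gibbs sampler.
#'
#' @param state a \code{\link{gibbs_state}}.
#' @param cm a \code{\link{count_matrix}}; \code{t_i} comes from
#'   \code{\link{length_offsets}}, \code{t_j} from the norm factors.
#' @param hyper a \code{\link{hyper_params}}.
#' @return scalar log posterior (finite for interior states).
#' @export
log_posterior <- function(state, cm, hyper) {
  x <- cm$counts
  p <- state$p
  if (any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  stopifnot(all(dim(x) == dim(p)))
  ti <- length_offsets(cm)
  tj <- cm$norm_factors
  rate <- outer(ti, tj) * (state$s * p)   # (s_i p_ij) row-scaled by s
  lik <- sum(x * log(rate) - rate - lgamma(x + 1))
  beta_term <- sum(ncol(p) * (lgamma(state$kon + state$koff) -
                                lgamma(state$kon) - lgamma(state$koff)) +
                     (state$kon - 1) * rowSums(log(p)) +
                     (state$koff - 1) * rowSums(log1p(-p)))
  gpr <- function(v, a, b) sum(-v / b + (a - 1) * log(v) - a * log(b) -
                                 lgamma(a))
  lik + beta_term +
    gpr(state$s, hyper$alpha_s, hyper$beta_s) +
    gpr(state$kon, hyper$alpha_kon, hyper$beta_kon) +
    gpr(state$koff, hyper$alpha_koff, hyper$beta_koff)
}

## Full-conditional log densities (reference R implementations used by the
## exported single-component updates and by tests; the compiled sampler has
## its own copies of the same expressions).
cond_logdens_p <- function(p, x, titjs, kon, koff) {
  (kon - 1) * log(p) + (koff - 1) * log1p(-p) +
    x * log(titjs * p) - titjs * p
}

cond_logdens_kon <- function(kon, a, b, koff, sum_log_p, J) {
  (a - 1) * log(kon) - kon / b +
    J * (lgamma(kon + koff) - lgamma(kon)) + (kon - 1) * sum_log_p
}

cond_logdens_koff <- function(koff, a, b, kon, sum_log_1mp, J) {
  (a - 1) * log(koff) - koff / b +
    J * (lgamma(kon + koff) - lgamma(koff)) + (koff - 1) * sum_log_1mp
}

cond_logdens_s <- function(s, a, b, sum_x, sum_tp) {
  (a - 1) * log(s) - s / b + sum_x * log(s) - s * sum_tp
}

#' Single-component Gibbs updates
#'
#' One slice-sampling update of one component of the state against its full
#' conditional: \code{update_p} refreshes the auxiliary variable
#' \code{p_ij} on its natural (0, 1) scale; \code{update_kon},
#' \code{update_koff} and \code{update_s} refresh the per-gene rates on the
#' log scale (with the Jacobian correction), where the slice width is in
#' log units. These are reference implementations used for testing and
#' didactic purposes; \code{\link{run_gibbs}} runs the same updates in
#' compiled code.
#'
#' @param i gene index; \code{j} cell index.
#' @param state a \code{\link{gibbs_state}}.
#' @param cm a \code{\link{count_matrix}}.
#' @param hyper a \code{\link{hyper_params}}.
#' @param width slice width (natural scale for p, log scale for rates).
#' @return the updated \code{\link{gibbs_state}}.
#' @name gibbs_updates
NULL

#' @rdname gibbs_updates
#' @param j cell index.
#' @export
update_p <- function(i, j, state, cm, width = 0.2) {
  titjs <- length_offsets(cm)[i] * cm$norm_factors[j] * state$s[i]
  f <- function(p) cond_logdens_p(p, cm$counts[i, j], titjs,
                                  state$kon[i], state$koff[i])
  state$p[i, j] <- slice_sample(f, state$p[i, j], width = width,
                                lower = 0, upper = 1)
  state
}

#' @rdname gibbs_updates
#' @export
update_kon <- function(i, state, hyper, width = 1) {
  J <- ncol(state$p)
  slp <- sum(log(state$p[i, ]))
  f <- function(th) cond_logdens_kon(exp(th), hyper$alpha_kon[i],
                                     hyper$beta_kon[i], state$koff[i],
                                     slp, J) + th
  state$kon[i] <- exp(slice_sample(f, log(state$kon[i]), width = width))
  state
}

#' @rdname gibbs_updates
#' @export
update_koff <- function(i, state, hyper, width = 1) {
  J <- ncol(state$p)
  sl1mp <- sum(log1p(-state$p[i, ]))
  f <- function(th) cond_logdens_koff(exp(th), hyper$alpha_koff[i],
                                      hyper$beta_koff[i], state$kon[i],
                                      sl1mp, J) + th
  state$koff[i] <- exp(slice_sample(f, log(state$koff[i]), width = width))
  state
}

#' @rdname gibbs_updates
#' @export
update_s <- function(i, state, cm, hyper, width = 1) {
  ti <- length_offsets(cm)[i]
  sum_tp <- sum(ti * cm$norm_factors * state$p[i, ])
  sum_x <- sum(cm$counts[i, ])
  f <- function(th) cond_logdens_s(exp(th), hyper$alpha_s[i],
                                   hyper$beta_s[i], sum_x, sum_tp) + th
  state$s[i] <- exp(slice_sample(f, log(state$s[i]), width = width))
  state
}

## Moment-flavored initial state inside the support.
initial_state <- function(cm) {
  xn <- sweep(cm$counts / outer(length_offsets(cm), cm$norm_factors), 1,
              1, "*")
  mx <- apply(xn, 1, max)
  p0 <- (xn + 0.5) / (mx + 1)
  p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  gibbs_state(p = p0, kon = rep(1, nrow(xn)), koff = rep(1, nrow(xn)),
              s = pmax(mx, 0.5))
}

#' Run the Gibbs sampler
#'
#' Systematic-scan Gibbs sampling of the hierarchical Poisson-beta model:
#' each iteration slice-updates every \code{p_ij}, then \code{k_on,i},
#' \code{k_off,i} and \code{s_i} for every gene, and records the per-gene
#' rate trajectories and the log-posterior trace. The sweep runs in
#' compiled code; with the same seed two runs are bit-identical.
#'
#' @param cm a \code{\link{count_matrix}}, normally filtered
#'   (\code{\link{filter_genes}}) with norm factors computed.
#' @param hyper a \code{\link{hyper_params}}; defaults to
#'   \code{hyper_params(cm)}.
#' @param n_iter total Gibbs iterations (default 10000).
#' @param burn_in iterations discarded by \code{\link{point_estimates}};
#'   default half of \code{n_iter}. The running posterior mean of
#'   \code{p_ij} is accumulated after this point.
#' @param seed optional integer seed (local RNG state).
#' @param width_p,width_log slice widths for p (natural scale) and the
#'   rates (log scale).
#' @param max_steps maximum slice step-outs.
#' @param verbose print progress every 1000 iterations.
#' @return object of class \code{"gibbs_chain"}: matrices \code{kon},
#'   \code{koff}, \code{s} (iterations x genes), \code{log_posterior}
#'   trace, post-burn-in \code{p_mean}, the final \code{state}, and the run
#'   settings.
#' @export
run_gibbs <- function(cm, hyper = NULL, n_iter = 10000, burn_in = n_iter %/% 2,
                      seed = NULL, width_p = 0.2, width_log = 1,
                      max_steps = 50L, verbose = FALSE) {
  if (is.null(hyper)) hyper <- hyper_params(cm)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  init <- initial_state(cm)
  res <- with_seed(seed, gibbs_core(
    cm$counts, length_offsets(cm), as.numeric(cm$norm_factors),
    hyper$alpha_s, hyper$beta_s, hyper$alpha_kon, hyper$beta_kon,
    hyper$alpha_koff, hyper$beta_koff,
    as.integer(n_iter), as.integer(burn_in),
    width_p, width_log, as.integer(max_steps),
    init$p, init$kon, init$koff, init$s, isTRUE(verbose)))
  gid <- rownames(cm$counts)
  colnames(res$kon) <- colnames(res$koff) <- colnames(res$s) <- gid
  dimnames(res$p_mean) <- dimnames(cm$counts)
  structure(list(kon = res$kon, koff = res$koff, s = res$s,
                 log_posterior = as.numeric(res$log_posterior),
                 p_mean = res$p_mean,
                 state = gibbs_state(res$p_final, res$kon_final,
                                     res$koff_final, res$s_final),
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 gene_ids = gid),
            class = "gibbs_chain")
}

#' @export
print.gibbs_chain <- function(x, ...) {
  cat("gibbs_chain:", x$n_iter, "iterations (burn-in", x$burn_in, "),",
      ncol(x$kon), "genes,", ncol(x$p_mean), "cells\n")
  cat("  final log posterior:",
      format(x$log_posterior[length(x$log_posterior)]), "\n")
  invisible(x)
}

#' Posterior point estimates from a Gibbs chain
#'
#' Per-gene posterior means of \code{k_on,i}, \code{k_off,i}, \code{s_i}
#' over the post-burn-in samples, with batch-means Monte-Carlo standard
#' errors, plus the derived burst summaries evaluated at the posterior
#' means. Posterior means of \code{p_ij} are the running averages
#' accumulated by \code{\link{run_gibbs}}.
#'
#' @param chain a \code{\link{run_gibbs}} result.
#' @param burn_in override the chain's burn-in (e.g. 0 to keep everything).
#' @return list with a per-gene \code{estimates} data.frame and the
#'   \code{p_mean} matrix.
#' @export
point_estimates <- function(chain, burn_in = chain$burn_in) {
  if (burn_in >= chain$n_iter)
    stop("burn-in leaves no samples", call. = FALSE)
  keep <- seq.int(burn_in + 1, chain$n_iter)
  post <- function(m) m[keep, , drop = FALSE]
  est <- data.frame(
    gene_id = chain$gene_ids,
    kon_mean = colMeans(post(chain$kon)),
    koff_mean = colMeans(post(chain$koff)),
    s_mean = colMeans(post(chain$s)),
    kon_se = apply(post(chain$kon), 2, batch_means_se),
    koff_se = apply(post(chain$koff), 2, batch_means_se),
    s_se = apply(post(chain$s), 2, batch_means_se),
    row.names = NULL, stringsAsFactors = FALSE)
  bs <- burst_summaries(est$kon_mean, est$koff_mean, est$s_mean)
  list(estimates = cbind(est, bs), p_mean = chain$p_mean)
}
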