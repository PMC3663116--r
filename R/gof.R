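#' Maximum-likelihood fits of the null count families
#'
#' \code{fit_poisson_mle} returns the sample mean (the Poisson MLE).
#' \code{fit_nb_mle} maximizes the negative-binomial log-likelihood by a
#' profile over the size parameter \code{r} (for fixed \code{r} the MLE of
#' the mean is the sample mean, giving the success probability in closed
#' form); the profile is optimized over \code{log r}. An underdispersed
#' sample (variance <= mean) has no interior NB maximum — the fit is
#' flagged degenerate and callers treat the gene as Poisson-consistent.
#'
#' @param x integer sample.
#' @return \code{fit_poisson_mle}: the rate estimate. \code{fit_nb_mle}: a
#'   list with \code{size}, \code{mu}, \code{prob} and a \code{degenerate}
#'   flag.
#' @export
fit_poisson_mle <- function(x) {
  if (length(x) < 1) stop("empty sample", call. = FALSE)
  mean(x)
}

#' @rdname fit_poisson_mle
#' @export
fit_nb_mle <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  m <- mean(x)
  v <- stats::var(x)
  if (!(v > m) || m == 0)
    return(list(size = Inf, mu = m, prob = 1, degenerate = TRUE))
  ## method-of-moments start: v = m + m^2/r
  r0 <- m^2 / (v - m)
  prof <- function(lr) sum(stats::dnbinom(x, size = exp(lr), mu = m,
                                          log = TRUE))
  opt <- stats::optimize(prof, interval = log(r0) + c(-12, 12), maximum = TRUE,
                         tol = 1e-10)
  r <- exp(opt$maximum)
  list(size = r, mu = m, prob = r / (r + m), degenerate = FALSE)
}

#' Kolmogorov-Smirnov statistic at the observed points
#'
#' \code{max_i |F_n(X_i) - F(X_i)|} where \code{F_n} is the
#' right-continuous empirical CDF of the sample and \code{F} the fitted
#' CDF, both evaluated at the data points only. This is the statistic whose
#' null distribution the parametric bootstrap supplies; no asymptotic table
#' is involved, so its discreteness needs no correction.
#'
#' @param x sample.
#' @param cdf vectorized cumulative distribution function.
#' @return the statistic, in [0, 1].
#' @export
ks_statistic <- function(x, cdf) {
  if (length(x) < 1) stop("empty sample", call. = FALSE)
  Fn <- stats::ecdf(x)
  max(abs(Fn(x) - cdf(x)))
}

nb_cdf <- function(fit) {
  if (fit$degenerate) function(q) stats::ppois(q, fit$mu)
  else function(q) stats::pnbinom(q, size = fit$size, mu = fit$mu)
}

#' Parametric-bootstrap goodness-of-fit P value
#'
#' Tests whether a count sample is consistent with a Poisson or negative
#' binomial distribution. The family is fitted by maximum likelihood and
#' the KS statistic computed; then \code{B} times, \code{n} draws are
#' simulated from the fitted distribution, the family refitted to them, and
#' the KS statistic of the bootstrap sample against its own refit recorded.
#' The P value is the fraction of bootstrap statistics strictly exceeding
#' the observed one (so it is a multiple of 1/B). A degenerate NB fit
#' (underdispersion) returns P = 1: a family that fits trivially cannot be
#' rejected.
#'
#' @param x integer sample, length >= 2.
#' @param family \code{"poisson"} or \code{"nb"}.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed optional integer seed (local RNG state).
#' @return bootstrap P value.
#' @export
bootstrap_gof <- function(x, family = c("poisson", "nb"), B = 1000,
                          seed = NULL) {
  family <- match.arg(family)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  with_seed(seed, {
    if (family == "poisson") {
      lam <- fit_poisson_mle(x)
      ks_obs <- ks_statistic(x, function(q) stats::ppois(q, lam))
      ks_boot <- vapply(seq_len(B), function(k) {
        xb <- stats::rpois(n, lam)
        ks_statistic(xb, function(q) stats::ppois(q, fit_poisson_mle(xb)))
      }, numeric(1))
    } else {
      fit <- fit_nb_mle(x)
      if (fit$degenerate) return(1)
      ks_obs <- ks_statistic(x, nb_cdf(fit))
      ks_boot <- vapply(seq_len(B), function(k) {
        xb <- stats::rnbinom(n, size = fit$size, mu = fit$mu)
        ks_statistic(xb, nb_cdf(fit_nb_mle(xb)))
      }, numeric(1))
    }
    mean(ks_boot > ks_obs)
  })
}

#' Identifiability of telegraph-model parameters
#'
#' A gene's three Poisson-beta parameters are statistically identifiable
#' only when its count distribution is distinguishable from the simpler
#' Poisson and negative binomial alternatives (fast promoter switching
#' collapses the model onto them). This draws \code{n} samples from the
#' Poisson-beta distribution at the given rates (typically posterior
#' means), runs both bootstrap goodness-of-fit tests, and declares the
#' parameters identifiable iff both families are rejected:
#' \code{max(p_poisson, p_nb) < alpha}.
#'
#' @param k_on,k_off,s scalar rates (or a single-row
#'   \code{\link{kinetic_params}} in \code{k_on}).
#' @param n number of Poisson-beta draws tested (default 1000).
#' @param B bootstrap replicates per family (default 1000).
#' @param alpha rejection threshold on the maximum P value (default 0.1).
#' @param seed optional integer seed.
#' @return a one-row data.frame (class \code{"gof_report"}) with
#'   \code{ks_poisson}, \code{p_poisson}, \code{ks_nb}, \code{p_nb},
#'   \code{n}, \code{B}, \code{identifiable}.
#' @export
classify_identifiability <- function(k_on, k_off = NULL, s = NULL, n = 1000,
                                     B = 1000, alpha = 0.1, seed = NULL) {
  pr <- unpack_params(k_on, k_off, s)
  check_rates(pr$k_on, pr$k_off, pr$s)
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1), 3)
  x <- rpobe(n, pr$k_on, pr$k_off, pr$s, seed = seeds[1])
  lam <- fit_poisson_mle(x)
  nbfit <- fit_nb_mle(x)
  rep <- data.frame(
    ks_poisson = ks_statistic(x, function(q) stats::ppois(q, lam)),
    p_poisson = bootstrap_gof(x, "poisson", B = B, seed = seeds[2]),
    ks_nb = ks_statistic(x, nb_cdf(nbfit)),
    p_nb = bootstrap_gof(x, "nb", B = B, seed = seeds[3]),
    n = n, B = B)
  rep$identifiable <- max(rep$p_poisson, rep$p_nb) < alpha
  class(rep) <- c("gof_report", "data.frame")
  rep
}

#' Identifiability screen over a table of genes
#'
#' Applies \code{\link{classify_identifiability}} to each row of a
#' \code{\link{kinetic_params}} table (one independent seed per gene,
#' derived from \code{seed}).
#'
#' @param params a \code{\link{kinetic_params}} table.
#' @inheritParams classify_identifiability
#' @return data.frame with one \code{gof_report} row per gene.
#' @export
classify_genes <- function(params, n = 1000, B = 1000, alpha = 0.1,
                           seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        nrow(params))
  out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i)
    classify_identifiability(params$k_on[i], params$k_off[i], params$s[i],
                             n = n, B = B, alpha = alpha, seed = seeds[i])))
  cbind(gene_id = params$gene_id, out)
}
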