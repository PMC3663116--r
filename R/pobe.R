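#' Kinetic parameters of the two-state promoter model
#'
#' Constructs and validates a per-gene table of telegraph-model rates. All
#' rates are expressed per mean mRNA lifetime, i.e. the decay rate is fixed
#' at 1 and \code{k_on}, \code{k_off} and \code{s} are dimensionless.
#'
#' @param k_on numeric vector of activation rates (off -> on), > 0.
#' @param k_off numeric vector of inactivation rates (on -> off), > 0.
#' @param s numeric vector of transcription rates while active, > 0.
#' @param gene_id optional character vector of gene identifiers.
#'
#' @return A \code{data.frame} of class \code{"kinetic_params"} with columns
#'   \code{gene_id}, \code{k_on}, \code{k_off}, \code{s}.
#' @export
kinetic_params <- function(k_on, k_off, s, gene_id = NULL) {
  n <- max(length(k_on), length(k_off), length(s))
  k_on <- rep_len(as.numeric(k_on), n)
  k_off <- rep_len(as.numeric(k_off), n)
  s <- rep_len(as.numeric(s), n)
  check_rates(k_on, k_off, s)
  if (is.null(gene_id)) gene_id <- sprintf("gene%03d", seq_len(n))
  out <- data.frame(gene_id = as.character(gene_id), k_on = k_on,
                    k_off = k_off, s = s, stringsAsFactors = FALSE)
  class(out) <- c("kinetic_params", "data.frame")
  out
}

check_rates <- function(k_on, k_off, s = 1) {
  if (any(!is.finite(k_on)) || any(k_on <= 0))
    stop("k_on must be finite and > 0", call. = FALSE)
  if (any(!is.finite(k_off)) || any(k_off <= 0))
    stop("k_off must be finite and > 0", call. = FALSE)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("s must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

## Accept either (k_on, k_off, s) vectors or a kinetic_params table in the
## first argument.
unpack_params <- function(k_on, k_off = NULL, s = NULL) {
  if (is.data.frame(k_on)) {
    list(k_on = k_on$k_on, k_off = k_on$k_off, s = k_on$s)
  } else {
    list(k_on = k_on, k_off = k_off, s = s)
  }
}

#' Fraction of time a gene spends in the active state
#'
#' For a promoter switching on at rate \code{k_on} and off at rate
#' \code{k_off}, the stationary active-state probability is
#' \code{k_on / (k_on + k_off)}.
#'
#' @param k_on activation rates, or a \code{\link{kinetic_params}} table.
#' @param k_off inactivation rates (ignored when a table is given).
#' @return numeric vector of probabilities in (0, 1).
#' @export
active_fraction <- function(k_on, k_off = NULL) {
  pr <- unpack_params(k_on, k_off)
  check_rates(pr$k_on, pr$k_off)
  pr$k_on / (pr$k_on + pr$k_off)
}

#' Closed-form moments of the Poisson-beta distribution
#'
#' Mean, variance, squared coefficient of variation and Fano factor of the
#' steady-state mRNA copy-number distribution of the telegraph model:
#' \deqn{E[x] = s k_{on}/(k_{on}+k_{off})}
#' \deqn{Var[x] = E[x] + s^2 k_{on} k_{off} /
#'   ((k_{on}+k_{off})^2 (k_{on}+k_{off}+1))}
#' The Fano factor is always >= 1: bursty transcription is at least
#' Poisson-dispersed.
#'
#' @inheritParams active_fraction
#' @param s transcription rates (ignored when a table is given).
#' @return data.frame with columns \code{mean}, \code{variance}, \code{cv2},
#'   \code{fano}.
#' @export
pobe_moments <- function(k_on, k_off = NULL, s = NULL) {
  pr <- unpack_params(k_on, k_off, s)
  check_rates(pr$k_on, pr$k_off, pr$s)
  ksum <- pr$k_on + pr$k_off
  m <- pr$s * pr$k_on / ksum
  v <- m + pr$s^2 * pr$k_on * pr$k_off / (ksum^2 * (ksum + 1))
  data.frame(mean = m, variance = v, cv2 = v / m^2, fano = v / m)
}

#' Burst-kinetics summaries
#'
#' Derived quantities of the telegraph model: burst size (mean mRNAs made
#' per on-period, \code{s/k_off}), burst frequency (\code{k_on}, bursts per
#' mRNA lifetime), and the stationary active/inactive state fractions.
#'
#' @inheritParams pobe_moments
#' @return data.frame with columns \code{burst_size}, \code{burst_frequency},
#'   \code{active_fraction}, \code{inactive_fraction}.
#' @export
burst_summaries <- function(k_on, k_off = NULL, s = NULL) {
  pr <- unpack_params(k_on, k_off, s)
  check_rates(pr$k_on, pr$k_off, pr$s)
  af <- pr$k_on / (pr$k_on + pr$k_off)
  data.frame(burst_size = pr$s / pr$k_off,
             burst_frequency = pr$k_on,
             active_fraction = af,
             inactive_fraction = 1 - af)
}

#' Sample from the Poisson-beta distribution
#'
#' Draws via the auxiliary-variable representation: \code{p ~ Beta(k_on,
#' k_off)}, then \code{x | p ~ Poisson(s p)}.
#'
#' @param n number of draws.
#' @param k_on,k_off,s scalar telegraph rates (or a single-row
#'   \code{\link{kinetic_params}} table in \code{k_on}).
#' @param seed optional integer; when given, sampling runs under a local RNG
#'   state seeded with it and the caller's RNG state is untouched.
#' @return integer vector of counts.
#' @export
rpobe <- function(n, k_on, k_off = NULL, s = NULL, seed = NULL) {
  pr <- unpack_params(k_on, k_off, s)
  check_rates(pr$k_on, pr$k_off, pr$s)
  with_seed(seed, {
    p <- stats::rbeta(n, pr$k_on, pr$k_off)
    stats::rpois(n, pr$s * p)
  })
}

#' Poisson-beta probability mass function
#'
#' Probability of observing \code{x} mRNA molecules under the telegraph
#' model at steady state (decay rate fixed to 1). The default evaluation
#' integrates \code{dpois(x, s p)} against the Beta(\code{k_on},
#' \code{k_off}) density by adaptive quadrature in log space, after a
#' power-law change of variables on each half of (0, 1) that removes the
#' beta endpoint singularities; this is stable across the full parameter
#' range. \code{method = "hyp1f1"} evaluates the confluent-hypergeometric
#' closed form through a log-space positive-term Kummer series and is
#' intended as an independent cross-check.
#'
#' @param x vector of non-negative integer counts.
#' @param k_on,k_off,s scalar telegraph rates (or a single-row
#'   \code{\link{kinetic_params}} table in \code{k_on}).
#' @param log if TRUE, return log-probabilities.
#' @param method \code{"quadrature"} (default) or \code{"hyp1f1"}.
#' @param rel.tol relative tolerance passed to the adaptive integrator.
#' @return numeric vector of (log-)probabilities, same length as \code{x}.
#' @export
dpobe <- function(x, k_on, k_off = NULL, s = NULL, log = FALSE,
                  method = c("quadrature", "hyp1f1"), rel.tol = 1e-10) {
  method <- match.arg(method)
  pr <- unpack_params(k_on, k_off, s)
  check_rates(pr$k_on, pr$k_off, pr$s)
  if (length(pr$k_on) != 1L)
    stop("dpobe takes scalar parameters", call. = FALSE)
  if (any(x < 0) || any(x != floor(x)))
    stop("x must be non-negative integers", call. = FALSE)
  lp <- switch(method,
    quadrature = vapply(x, dpobe_quad1, numeric(1), k_on = pr$k_on,
                        k_off = pr$k_off, s = pr$s, rel.tol = rel.tol),
    hyp1f1 = dpobe_1f1(x, pr$k_on, pr$k_off, pr$s))
  ## a non-finite closed-form value falls back to quadrature rather than
  ## propagating NaN
  bad <- !is.finite(lp) & !(lp == -Inf)
  if (any(bad))
    lp[bad] <- vapply(x[bad], dpobe_quad1, numeric(1), k_on = pr$k_on,
                      k_off = pr$k_off, s = pr$s, rel.tol = rel.tol)
  if (log) lp else exp(lp)
}

## log pmf at a single x by adaptive quadrature over the mixing variable p,
## split at p = 1/2.  A half whose beta shape parameter is < 1 has an
## integrable endpoint singularity there; it is removed exactly by the
## power substitution v = p^k_on (left) or w = (1-p)^k_off (right).  Halves
## with shape >= 1 are integrated on the p scale directly.  Each piece is
## stabilised by subtracting the analytic maximum of its log integrand.
dpobe_quad1 <- function(x, k_on, k_off, s, rel.tol = 1e-10) {
  lbet <- lbeta(k_on, k_off)
  ## mode of p^A (1-p)^B e^{-sp} (up to constants): root of the quadratic
  ## s p^2 - (s + A + B) p + A = 0 lying in (0, 1)
  peak_p <- function(A, B) {
    if (A <= 0) return(0)
    bq <- s + A + B
    disc <- bq^2 - 4 * s * A
    if (disc < 0 || s == 0) return(min(A / (A + max(B, 0) + 1e-12), 1))
    min(max((bq - sqrt(disc)) / (2 * s), 0), 1)
  }
  quad_piece <- function(lf, upper, peak, lognorm) {
    grid <- upper * c(1e-12, 1e-9, 1e-6, 1e-3,
                      seq(0.005, 0.995, length.out = 80))
    if (peak > 0 && peak < upper)
      grid <- c(grid, pmin(peak * c(0.99, 1, 1.01), upper))
    lg <- lf(grid)
    m <- max(lg[is.finite(lg)], -Inf)
    if (!is.finite(m)) return(-Inf)
    val <- stats::integrate(function(v) exp(pmin(lf(v) - m, 700)), 0, upper,
                            rel.tol = rel.tol, abs.tol = 0,
                            subdivisions = 400L, stop.on.error = FALSE)$value
    if (val <= 0) return(-Inf)
    m + log(val) + lognorm
  }
  left <- if (k_on >= 1) {
    lf <- function(p) (k_on - 1) * log(p) + (k_off - 1) * log1p(-p) +
      stats::dpois(x, s * p, log = TRUE)
    quad_piece(lf, 0.5, peak_p(k_on - 1 + x, k_off - 1), -lbet)
  } else {
    lf <- function(v) {
      p <- exp(log(v) / k_on)
      (k_off - 1) * log1p(-p) + stats::dpois(x, s * p, log = TRUE)
    }
    quad_piece(lf, 0.5^k_on, peak_p(x, k_off - 1)^k_on, -log(k_on) - lbet)
  }
  right <- if (k_off >= 1) {
    lf <- function(p) (k_on - 1) * log(p) + (k_off - 1) * log1p(-p) +
      stats::dpois(x, s * p, log = TRUE)
    ## integrate over p in (1/2, 1) via q = 1 - p
    lfq <- function(q) lf(1 - q)
    quad_piece(lfq, 0.5, 1 - peak_p(k_on - 1 + x, k_off - 1), -lbet)
  } else {
    lf <- function(w) {
      q <- exp(log(w) / k_off)   # q = 1 - p
      (k_on - 1) * log1p(-q) + stats::dpois(x, s * (1 - q), log = TRUE)
    }
    quad_piece(lf, 0.5^k_off, (1 - peak_p(k_on - 1 + x, 0))^k_off,
               -log(k_off) - lbet)
  }
  logspace_add(left, right)
}

## closed form via the confluent hypergeometric function:
## P(x) = s^x e^{-s} G(k_on+x) G(k_on+k_off) /
##        (x! G(k_on+k_off+x) G(k_on)) * 1F1(k_off, k_on+k_off+x; s)
## 1F1 with positive arguments has all-positive series terms, summed in
## log space.
dpobe_1f1 <- function(x, k_on, k_off, s) {
  vapply(x, function(xi) {
    b <- k_on + k_off + xi
    xi * log(s) - s + lgamma(k_on + xi) + lgamma(k_on + k_off) -
      lgamma(xi + 1) - lgamma(b) - lgamma(k_on) + log_hyp1f1_series(k_off, b, s)
  }, numeric(1))
}

## log 1F1(a, b; z) for a, b, z > 0 by direct series with log-sum-exp.
log_hyp1f1_series <- function(a, b, z) {
  nmax <- as.integer(ceiling(z + 40 * sqrt(z + 1) + 200))
  n <- 0:nmax
  lt <- lgamma(a + n) - lgamma(a) - (lgamma(b + n) - lgamma(b)) +
    n * log(z) - lgamma(n + 1)
  m <- max(lt)
  ## terms are eventually decaying like z^n/n!; nmax leaves tail < 1e-15
  m + log(sum(exp(lt - m)))
}

logspace_add <- function(la, lb) {
  if (la == -Inf) return(lb)
  if (lb == -Inf) return(la)
  m <- max(la, lb)
  m + log1p(exp(min(la, lb) - m))
}

#' Truncation point covering essentially all Poisson-beta mass
#'
#' Upper count bound for summing the pmf over a finite range: the larger of
#' \code{mean + 12 sd} and an extreme upper quantile of Poisson(\code{s}).
#' Because \code{x | p ~ Poisson(s p)} with \code{p <= 1}, the count is
#' stochastically dominated by Poisson(\code{s}), so the Poisson quantile
#' bounds the tail mass below 1e-9 even in the heavy-tailed regime (tiny
#' \code{k_on} with large \code{k_off}) where a moment-based rule fails.
#'
#' @inheritParams pobe_moments
#' @return integer upper bound.
#' @export
pobe_truncation <- function(k_on, k_off = NULL, s = NULL) {
  mo <- pobe_moments(k_on, k_off, s)
  pr <- unpack_params(k_on, k_off, s)
  as.integer(ceiling(pmax(mo$mean + 12 * sqrt(mo$variance),
                          stats::qpois(1e-10, pr$s, lower.tail = FALSE) + 1)))
}
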