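#' Univariate slice sampler (step-out and shrinkage)
#'
#' One update of Neal's slice sampler: draw an auxiliary level under the
#' density at the current point, step out an interval of width \code{width}
#' until it brackets the slice (at most \code{max_steps} expansions per
#' side), then sample by shrinkage. Leaves \code{exp(logdensity)}
#' invariant. Consumes the ambient RNG stream, so runs are reproducible
#' under \code{set.seed}.
#'
#' @param logdensity function of one real argument returning the log target
#'   (up to a constant); may return \code{-Inf} outside the support.
#' @param current current value; \code{logdensity(current)} must be finite.
#' @param width initial bracket width.
#' @param max_steps maximum step-out expansions per side.
#' @param lower,upper optional hard support bounds to clamp the bracket.
#' @return new value of the variable.
#' @export
slice_sample <- function(logdensity, current, width = 1, max_steps = 50L,
                         lower = -Inf, upper = Inf) {
  lf0 <- logdensity(current)
  if (!is.finite(lf0))
    stop("logdensity not finite at the current point", call. = FALSE)
  logy <- lf0 - stats::rexp(1)
  L <- current - width * stats::runif(1)
  R <- L + width
  J <- floor(max_steps * stats::runif(1))
  K <- max_steps - 1 - J
  while (J > 0 && L > lower && logdensity(L) > logy) { L <- L - width; J <- J - 1 }
  while (K > 0 && R < upper && logdensity(R) > logy) { R <- R + width; K <- K - 1 }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- L + stats::runif(1) * (R - L)
    if (logdensity(x1) > logy) return(x1)
    if (x1 < current) L <- x1 else R <- x1
    if (R - L < 1e-300) return(current)
  }
}
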