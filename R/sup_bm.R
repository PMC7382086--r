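#' Tail probability of the supremum of absolute Brownian motion
#'
#' For standard Brownian motion \eqn{M} on \eqn{[0,1]},
#' \deqn{P\big[\sup_{t}|M(t)| > x\big] = 1 - \frac{4}{\pi}
#'   \sum_{a=0}^{\infty} \frac{(-1)^a}{2a+1}
#'   e^{-\pi^2 (2a+1)^2 / (8x^2)},}
#' the classical boundary-crossing series.  The series is truncated at
#' \deqn{m = \max\Big\{\Big\lceil \frac{x\sqrt2}{\pi}
#'   \sqrt{\log\frac{1}{\pi\varepsilon}} - \frac12 \Big\rceil,\, 1\Big\},}
#' which bounds the remainder by \eqn{\varepsilon}.
#'
#' @param x positive quantile (vectorised).
#' @param epsilon permissible truncation error of the series.
#' @return A list of class \code{"sup_bm_tail"}: \code{x}, \code{epsilon},
#'   \code{m} (truncation index per element) and \code{probability}.
#' @examples
#' sup_bm_tail(2.2414)$probability   # ~ 0.05
#' @export
sup_bm_tail <- function(x, epsilon = 1e-10) {
  if (any(!is.finite(x) | x <= 0)) stop("'x' must be positive")
  if (!is.finite(epsilon) || epsilon <= 0) stop("'epsilon' must be positive")
  m <- pmax(ceiling(x * sqrt(2) / pi * sqrt(log(1 / (pi * epsilon))) - 0.5),
            1)
  prob <- vapply(seq_along(x), function(i) {
    a <- 0:m[i]
    s <- sum((-1)^a / (2 * a + 1) *
               exp(-pi^2 * (2 * a + 1)^2 / (8 * x[i]^2)))
    min(max(1 - 4 / pi * s, 0), 1)
  }, numeric(1))
  structure(list(x = x, epsilon = epsilon, m = m, probability = prob),
            class = "sup_bm_tail")
}

#' Critical value of the supremum of absolute Brownian motion
#'
#' The quantile \eqn{V_{1-\alpha/2}} with
#' \eqn{P[\sup|M(t)| > V] = \alpha}, found by bracketed root search on the
#' series tail probability.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param epsilon tolerance for the root and the series truncation.
#' @return The critical value (about 2.2414 at \code{alpha = 0.05}).
#' @export
sup_bm_critical_value <- function(alpha, epsilon = 1e-10) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  f <- function(x) sup_bm_tail(x, epsilon)$probability - alpha
  lo <- 1e-3
  hi <- 10
  while (f(hi) > 0) hi <- hi * 2   # tail(10) < 1e-8, loop is a formality
  stats::uniroot(f, c(lo, hi), tol = max(epsilon, .Machine$double.eps^0.75)
                 )$root
}

#' @export
print.sup_bm_tail <- function(x, ...) {
  for (i in seq_along(x$x))
    cat(sprintf("P[sup|M| > %.6g] = %.8g  (m = %d, eps = %g)\n",
                x$x[i], x$probability[i], x$m[i], x$epsilon))
  invisible(x)
}
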