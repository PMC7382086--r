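#' Sample size for the basic RMTL difference test
#'
#' Closed-form total sample size for detecting an RMTL difference
#' \eqn{\Delta} with the normal-approximation test:
#' \deqn{n = (1+r)\,\frac{(z_{1-\beta} + z_{1-\alpha/2})^2}
#'   {\Delta^2 / (\sigma_1^2 + r^{-1}\sigma_2^2)},}
#' where \eqn{r = n_2/n_1} is the allocation ratio and
#' \eqn{\sigma_k^2} are the per-observation RMTL variances
#' (\code{var_pobs} of [rmtl()], estimable from pilot data via
#' [pilot_design()]).  Groups are rounded up separately:
#' \eqn{n_1 = \lceil n/(1+r)\rceil}, \eqn{n_2 = \lceil r\,n/(1+r)\rceil}.
#'
#' @param delta assumed RMTL difference (nonzero), in time units.
#' @param var1,var2 per-observation RMTL variances of the two groups
#'   (time-squared units).
#' @param alpha two-sided type-I error, default 0.05.
#' @param power target power \eqn{1-\beta}, default 0.8.
#' @param r allocation ratio \eqn{n_2/n_1}, default 1.
#' @return A \code{"cr_samplesize"} object: \code{n1}, \code{n2},
#'   \code{n_total}, \code{n_raw} (unrounded), \code{method}, \code{xi} (1
#'   for this method) and the design parameters.
#' @examples
#' samplesize_diff(delta = 1, var1 = 4, var2 = 4)  # n_total = 126
#' @export
samplesize_diff <- function(delta, var1, var2, alpha = 0.05, power = 0.8,
                            r = 1) {
  .check_design(delta, var1, var2, alpha, power, r)
  zb <- stats::qnorm(power)
  za <- stats::qnorm(1 - alpha / 2)
  n_raw <- (1 + r) * (zb + za)^2 / (delta^2 / (var1 + var2 / r))
  .ss_obj("diff", n_raw, r, xi = 1,
          params = list(delta = delta, var1 = var1, var2 = var2,
                        alpha = alpha, power = power, r = r))
}

.check_design <- function(delta, var1, var2, alpha, power, r) {
  if (!is.finite(delta) || delta == 0)
    stop("'delta' must be nonzero (zero effect gives infinite n)")
  if (!is.finite(var1) || var1 <= 0 || !is.finite(var2) || var2 <= 0)
    stop("'var1' and 'var2' must be positive")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  if (!is.finite(r) || r <= 0) stop("'r' must be positive")
  invisible(TRUE)
}

.ss_obj <- function(method, n_raw, r, xi, params, diag = list()) {
  n1 <- ceiling(n_raw / (1 + r))
  n2 <- ceiling(r * n_raw / (1 + r))
  structure(c(list(method = method, n1 = n1, n2 = n2, n_total = n1 + n2,
                   n_raw = n_raw, xi = xi, params = params), diag),
            class = "cr_samplesize")
}

#' Drift solution for the supremum-test power equation
#'
#' For a Brownian motion with drift \eqn{\eta} observed on \eqn{[0,1]} and
#' critical value \eqn{V = V_{1-\alpha/2}} of the supremum of the absolute
#' standard Brownian motion, the power equation is
#' \deqn{Y(\eta) = \bar\Phi(V - \eta) + e^{2\eta V}\bar\Phi(V + \eta)
#'   = 1 - \beta.}
#' It is solved by Newton-Raphson started at the fixed-time drift
#' \eqn{\tilde\eta = z_{1-\alpha/2} + z_{1-\beta}}, using
#' \eqn{Y'(x) = \varphi(V-x) + 2V e^{2Vx}\bar\Phi(V+x) - e^{2Vx}\varphi(V+x)}
#' and safeguarded by bisection inside
#' \eqn{[\tilde\eta, \tilde\eta + 5]}.
#'
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @param epsilon convergence tolerance on the Newton step.
#' @param max_iter iteration cap before the bisection fallback reports
#'   failure.
#' @return List with \code{eta}, \code{eta_tilde}, \code{V} and
#'   \code{iterations}.
#' @export
solve_eta <- function(alpha = 0.05, power = 0.8, epsilon = 1e-10,
                      max_iter = 100L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  V <- sup_bm_critical_value(alpha, epsilon)
  eta_tilde <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  # exp(2*V*x) overflows only for x far outside the bracket; the products
  # below stay finite because Phi-bar and phi decay faster.
  Y <- function(x) stats::pnorm(V - x, lower.tail = FALSE) +
    exp(2 * V * x) * stats::pnorm(V + x, lower.tail = FALSE)
  Yp <- function(x) stats::dnorm(V - x) +
    2 * V * exp(2 * V * x) * stats::pnorm(V + x, lower.tail = FALSE) -
    exp(2 * V * x) * stats::dnorm(V + x)
  lo <- eta_tilde
  hi <- eta_tilde + 5
  x <- eta_tilde
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter)
      stop("Newton-Raphson failed to converge for eta (alpha = ", alpha,
           ", power = ", power, "); last x = ", x)
    fx <- Y(x) - power
    # keep the bracket current for the fallback
    if (fx < 0) lo <- max(lo, x) else hi <- min(hi, x)
    step <- fx / Yp(x)
    xn <- x - step
    if (!is.finite(xn) || xn < lo || xn > hi) xn <- (lo + hi) / 2
    if (abs(xn - x) <= epsilon) {
      x <- xn
      break
    }
    x <- xn
  }
  list(eta = x, eta_tilde = eta_tilde, V = V, iterations = it)
}

#' Sample size for the supremum RMTL difference test
#'
#' The supremum test needs more subjects than the fixed-time test by the
#' inflation factor \eqn{\xi = \eta^2 / \tilde\eta^2}, where \eqn{\eta}
#' solves the drifted-Brownian-motion power equation ([solve_eta()]) and
#' \eqn{\tilde\eta = z_{1-\alpha/2} + z_{1-\beta}}.  \eqn{\xi} depends only
#' on \eqn{(\alpha, 1-\beta)}, never on the data: the effect-size terms
#' cancel in the ratio.  The returned size is \eqn{n = \xi\,\tilde n} with
#' \eqn{\tilde n} the unrounded [samplesize_diff()] size, then per-group
#' ceiling.
#'
#' @inheritParams samplesize_diff
#' @param epsilon tolerance passed to [solve_eta()].
#' @return A \code{"cr_samplesize"} object with diagnostics \code{eta},
#'   \code{eta_tilde} and \code{V}.
#' @export
samplesize_sdiff <- function(delta, var1, var2, alpha = 0.05, power = 0.8,
                             r = 1, epsilon = 1e-10) {
  base <- samplesize_diff(delta, var1, var2, alpha, power, r)
  sol <- solve_eta(alpha, power, epsilon)
  xi <- (sol$eta / sol$eta_tilde)^2
  .ss_obj("sdiff", xi * base$n_raw, r, xi = xi, params = base$params,
          diag = list(eta = sol$eta, eta_tilde = sol$eta_tilde, V = sol$V))
}

#' Design parameters estimated from pilot data
#'
#' Estimates the RMTL difference and the per-group per-observation variances
#' at a given restriction time from a two-group pilot sample, for use with
#' [samplesize_diff()] / [samplesize_sdiff()].
#'
#' @param sample a two-group \code{"cr_sample"}.
#' @param tau restriction time; \code{NULL} selects [default_tau()].
#' @param r planned allocation ratio for the new trial.
#' @return List with \code{delta} (non-reference minus reference),
#'   \code{var1}, \code{var2} (per-observation), \code{tau} and \code{r}.
#' @export
pilot_design <- function(sample, tau = NULL, r = 1) {
  rs <- .resolve_two_groups(sample, tau)
  fits <- lapply(rs$groups, rmtl, tau = rs$tau)
  delta <- fits[[2]]$value - fits[[1]]$value
  if (delta == 0)
    stop("pilot groups have identical RMTL; no effect size to design for")
  list(delta = delta, var1 = fits[[1]]$var_pobs, var2 = fits[[2]]$var_pobs,
       tau = rs$tau, r = r)
}

#' @export
print.cr_samplesize <- function(x, ...) {
  lab <- if (x$method == "diff") "basic difference test"
         else "supremum difference test"
  cat(sprintf("Sample size (%s): n1 = %d, n2 = %d, total = %d\n",
              lab, x$n1, x$n2, x$n_total))
  p <- x$params
  cat(sprintf("  delta = %.4g, var1 = %.4g, var2 = %.4g, alpha = %g, power = %g, r = %g\n",
              p$delta, p$var1, p$var2, p$alpha, p$power, p$r))
  if (x$method == "sdiff")
    cat(sprintf("  xi = %.4f (eta = %.4f, eta~ = %.4f, V = %.4f)\n",
                x$xi, x$eta, x$eta_tilde, x$V))
  invisible(x)
}
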