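## Piecewise-Weibull distribution, parameterised by an additive cumulative
## hazard that is continuous at the breakpoints: on segment j with left
## endpoint b_{j-1}, H(t) = H(b_{j-1}) + ((t - b_{j-1})/scale_j)^shape_j.
## A single segment is an ordinary Weibull; shape 1 an exponential.

.pw_check <- function(shape, scale, breaks) {
  J <- length(shape)
  if (length(scale) != J) stop("'shape' and 'scale' lengths differ")
  if (length(breaks) != J - 1L)
    stop("'breaks' must have one fewer element than 'shape'")
  if (any(!is.finite(shape) | shape <= 0) ||
      any(!is.finite(scale) | scale <= 0))
    stop("shapes and scales must be positive")
  if (J > 1L && (any(breaks <= 0) || is.unsorted(breaks, strictly = TRUE)))
    stop("'breaks' must be strictly increasing and positive")
  invisible(TRUE)
}

# cumulative hazard at the segment starts: H(b_0)=0, H(b_1), ...
.pw_Hbreaks <- function(shape, scale, breaks) {
  b <- c(0, breaks)
  cumsum(c(0, ((breaks - b[-length(b)]) / scale[-length(shape)])^
              shape[-length(shape)]))
}

#' Piecewise-Weibull distribution
#'
#' Distribution with piecewise-Weibull cumulative hazard: on the j-th
#' segment starting at breakpoint \eqn{b_{j-1}} (with \eqn{b_0 = 0}),
#' \eqn{H(t) = H(b_{j-1}) + ((t - b_{j-1})/\mathrm{scale}_j)^{\mathrm{shape}_j}}
#' and \eqn{F(t) = 1 - e^{-H(t)}}, continuous at the breakpoints.  With a
#' single segment this is the ordinary Weibull.  The quantile function
#' inverts the hazard segment-by-segment in closed form, so random
#' generation is exact inverse-transform sampling.
#'
#' @param q,p,n quantiles, probabilities, number of draws.
#' @param shape,scale positive segment parameters (equal length).
#' @param breaks strictly increasing interior breakpoints (one fewer than
#'   segments); omit for a plain Weibull.
#' @return \code{ppwweib} the CDF, \code{qpwweib} the quantile function,
#'   \code{rpwweib} random draws.
#' @examples
#' qpwweib(0.5, shape = 1, scale = 2)          # exponential median
#' ppwweib(3, shape = c(1, 1), scale = c(6.7, 19), breaks = 3)
#' @export
ppwweib <- function(q, shape, scale, breaks = numeric(0)) {
  .pw_check(shape, scale, breaks)
  b <- c(0, breaks)
  Hb <- .pw_Hbreaks(shape, scale, breaks)
  j <- pmin(findInterval(q, b), length(shape))
  j[q <= 0] <- 1L
  H <- Hb[j] + (pmax(q - b[j], 0) / scale[j])^shape[j]
  1 - exp(-H)
}

#' @rdname ppwweib
#' @export
qpwweib <- function(p, shape, scale, breaks = numeric(0)) {
  .pw_check(shape, scale, breaks)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must be in [0, 1]")
  b <- c(0, breaks)
  Hb <- .pw_Hbreaks(shape, scale, breaks)
  Ht <- -log1p(-p)
  j <- pmin(findInterval(Ht, Hb), length(shape))
  j[Ht <= 0] <- 1L
  b[j] + scale[j] * pmax(Ht - Hb[j], 0)^(1 / shape[j])
}

#' @rdname ppwweib
#' @export
rpwweib <- function(n, shape, scale, breaks = numeric(0)) {
  qpwweib(stats::runif(n), shape, scale, breaks)
}

#' Built-in simulation scenarios
#'
#' Six two-group competing-risks scenarios distinguished by the shape of the
#' event-of-interest CIFs \eqn{I_1(t) = p_1 F(t)} (conditional
#' piecewise-Weibull \eqn{F}, cause drawn Bernoulli with
#' \eqn{p_1 = I_1(\infty)}):
#' \describe{
#'   \item{A}{identical groups (null; type-I error).}
#'   \item{B}{ordered difference over the whole window, roughly proportional
#'     sub-distribution hazards.}
#'   \item{C}{non-proportional ordered difference (one group rises early,
#'     the other late, same plateau).}
#'   \item{D}{early difference, converging late.}
#'   \item{E}{late difference (both CIFs near zero early).}
#'   \item{F}{crossing CIFs whose integrated difference nearly cancels at
#'     the typical restriction time (group 1 rises early then stalls;
#'     group 2 overtakes).}
#' }
#' The competing event is Weibull(1, 12) in every group and scenario.  Time
#' units are arbitrary study time (months, say).
#'
#' @return Named list of scenario parameter sets; each group entry carries
#'   \code{cause1}/\code{cause2} piecewise-Weibull parameters and \code{p1}.
#' @export
cr_scenarios <- function() {
  w <- function(shape, scale, breaks = numeric(0))
    list(shape = shape, scale = scale, breaks = breaks)
  comp <- w(1, 12)
  g <- function(c1, p1 = 0.7) list(cause1 = c1, cause2 = comp, p1 = p1)
  list(
    A = list(g1 = g(w(1.2, 10)), g2 = g(w(1.2, 10))),
    B = list(g1 = g(w(1.5, 14)), g2 = g(w(1.5, 8))),
    C = list(g1 = g(w(0.6, 14)), g2 = g(w(1.8, 10))),
    D = list(g1 = g(w(1.4, 10)), g2 = g(w(0.5, 10))),
    E = list(g1 = g(w(3, 14)),   g2 = g(w(3, 9))),
    F = list(g1 = g(w(c(1, 1), c(6.7, 19), breaks = 3)),
             g2 = g(w(2.2, 9)))
  )
}

#' Assemble a simulation configuration
#'
#' Combines a scenario from [cr_scenarios()] (or user-supplied group
#' parameters) with group sizes and a censoring target.  When
#' \code{censoring > 0} the uniform censoring upper bound is calibrated by
#' [calibrate_censoring()] (identical for both groups), which consumes
#' random draws: seed the session first for reproducibility.
#'
#' @param scenario scenario label "A".."F", or a list with elements
#'   \code{g1}, \code{g2} in the registry format.
#' @param n1,n2 group sizes.
#' @param censoring target censoring proportion in \eqn{[0, 0.9]}; 0 means
#'   no censoring.
#' @param ndraws Monte-Carlo draws used for censoring calibration.
#' @return A \code{"cr_config"} list.
#' @export
scenario_config <- function(scenario = "A", n1 = 100, n2 = 100,
                            censoring = 0, ndraws = 1e5) {
  if (is.character(scenario)) {
    reg <- cr_scenarios()
    if (!scenario %in% names(reg)) stop("unknown scenario '", scenario, "'")
    par <- reg[[scenario]]
    lab <- scenario
  } else {
    par <- scenario
    lab <- "custom"
  }
  stopifnot(is.list(par$g1), is.list(par$g2), n1 >= 1, n2 >= 1)
  cfg <- structure(list(scenario = lab, g1 = par$g1, g2 = par$g2,
                        n1 = as.integer(n1), n2 = as.integer(n2),
                        censoring = censoring, censor_upper = NULL),
                   class = "cr_config")
  if (censoring > 0)
    cfg$censor_upper <- calibrate_censoring(cfg, censoring, ndraws = ndraws)
  cfg
}

# latent event-time draws from the config's mixture (cause then conditional
# time), pooled over groups with n1:n2 weights
.latent_draws <- function(config, ndraws) {
  n1 <- round(ndraws * config$n1 / (config$n1 + config$n2))
  draw <- function(gp, n) {
    cause1 <- stats::runif(n) < gp$p1
    tt <- numeric(n)
    for (cs in c("cause1", "cause2")) {
      sel <- if (cs == "cause1") cause1 else !cause1
      pw <- gp[[cs]]
      if (any(sel)) tt[sel] <- rpwweib(sum(sel), pw$shape, pw$scale,
                                       pw$breaks)
    }
    tt
  }
  c(draw(config$g1, n1), draw(config$g2, ndraws - n1))
}

#' Calibrate the uniform censoring upper bound
#'
#' Finds \code{b} such that, with censoring times \eqn{C \sim U(0, b)}
#' applied identically to both groups, the expected censoring proportion
#' \eqn{E[\min(T/b, 1)]} over the config's latent event-time mixture matches
#' the target.  The expectation is estimated once on \code{ndraws}
#' Monte-Carlo draws of \eqn{T} and then solved exactly in \code{b}
#' (monotone decreasing), so the realised tolerance is Monte-Carlo error
#' only.
#'
#' @param config a \code{"cr_config"} (its \code{censor_upper} is ignored).
#' @param target target censoring proportion in \eqn{[0, 0.9]}.
#' @param tol root-finding tolerance on the proportion.
#' @param ndraws Monte-Carlo draws.
#' @return The upper bound \code{b}, or \code{NULL} for target 0.
#' @export
calibrate_censoring <- function(config, target, tol = 1e-4, ndraws = 1e5) {
  if (!is.numeric(target) || target < 0 || target > 0.9)
    stop("'target' censoring rate must be in [0, 0.9]")
  if (target == 0) return(NULL)
  tt <- .latent_draws(config, ndraws)
  f <- function(b) mean(pmin(tt / b, 1)) - target
  hi <- max(tt) / target   # rate(hi) <= mean(tt)/hi < target
  stats::uniroot(f, c(1e-8, hi), tol = tol)$root
}

#' Draw one group's sample under a configuration
#'
#' Two-stage generation: the cause of failure is Bernoulli
#' (event of interest with probability \eqn{p_1}), the latent time is an
#' exact inverse-transform draw from that cause's conditional
#' piecewise-Weibull distribution, and the uniform censoring time (if any)
#' truncates it: the record is \eqn{(\min(T, C), \delta)} with \eqn{\delta =
#' 0} when censored, else the cause code.
#'
#' @param config a \code{"cr_config"}.
#' @param group 1 or 2.
#' @param n override of the group size.
#' @return A one-group \code{"cr_sample"}.
#' @export
sample_group <- function(config, group, n = NULL) {
  stopifnot(inherits(config, "cr_config"), group %in% c(1, 2))
  gp <- if (group == 1) config$g1 else config$g2
  if (is.null(n)) n <- if (group == 1) config$n1 else config$n2
  cause <- ifelse(stats::runif(n) < gp$p1, 1L, 2L)
  tt <- numeric(n)
  for (cs in 1:2) {
    sel <- cause == cs
    pw <- gp[[c("cause1", "cause2")[cs]]]
    if (any(sel)) tt[sel] <- rpwweib(sum(sel), pw$shape, pw$scale, pw$breaks)
  }
  if (!is.null(config$censor_upper)) {
    cc <- stats::runif(n, 0, config$censor_upper)
    cens <- cc < tt
    tt <- pmin(tt, cc)
    cause[cens] <- 0L
  }
  cr_sample(tt, cause)
}

#' Draw a full two-group study
#' @param config a \code{"cr_config"}.
#' @param labels group labels (reference first).
#' @return A two-group \code{"cr_sample"}.
#' @export
simulate_cr_study <- function(config, labels = c("1", "2")) {
  bind_groups(sample_group(config, 1), sample_group(config, 2),
              labels = labels)
}

# fast paired evaluation of both tests on raw vectors, used by the
# replication loops; returns NA p-values on degenerate replicates
.fast_tests <- function(t1, s1, t2, s2, rho = 0.5, epsilon = 1e-10) {
  e1 <- t1[s1 == 1L]
  e2 <- t2[s2 == 1L]
  if (!length(e1) || !length(e2))
    return(c(diff = NA_real_, sdiff = NA_real_))
  tau <- min(max(e1), max(e2))
  core1 <- .cr_core(t1, s1)
  core2 <- .cr_core(t2, s2)
  i1 <- .step_integrals(core1$time, core1$cif, tau, 0)
  i2 <- .step_integrals(core2$time, core2$cif, tau, 0)
  v1 <- max(2 * tau * i1[["int"]] - 2 * i1[["tint"]] - i1[["int"]]^2, 0)
  v2 <- max(2 * tau * i2[["int"]] - 2 * i2[["tint"]] - i2[["int"]]^2, 0)
  v <- v1 / core1$n + v2 / core2$n
  delta <- i2[["int"]] - i1[["int"]]
  p_diff <- if (v > 0) 2 * stats::pnorm(-abs(delta) / sqrt(v)) else NA_real_
  m <- tryCatch(.sdiff_machinery_cores(core1, core2, tau),
                error = function(e) NULL)
  p_sdiff <- NA_real_
  if (!is.null(m)) {
    s2s <- tryCatch(.sigma_from_machinery(m, rho), error = function(e) NA)
    if (is.finite(s2s)) {
      qs <- max(abs(m$delta)) / s2s
      p_sdiff <- if (qs <= 0) 1 else sup_bm_tail(qs, epsilon)$probability
    }
  }
  c(diff = p_diff, sdiff = p_sdiff)
}

.sdiff_machinery_cores <- function(core1, core2, tau) {
  ev <- sort(unique(c(core1$time[core1$d_all > 0],
                      core2$time[core2$d_all > 0])))
  ev <- ev[ev <= tau]
  if (length(ev) == 0L) stop("no events before tau")
  g <- if (ev[length(ev)] < tau) c(ev, tau) else ev
  K <- length(g) - 1L
  s <- g[seq_len(K)]
  w <- diff(g)
  D <- .step_at(core2$time, core2$cif, s, 0) -
       .step_at(core1$time, core1$cif, s, 0)
  V <- .cif_var_at(core2, s) + .cif_var_at(core1, s)
  list(time = s, width = w, delta = cumsum(D * w), vsum = V, tau = tau)
}

#' Rejection-rate study
#'
#' Repeatedly simulates the configured two-group study, sets the restriction
#' time to the default rule (minimum over groups of the last
#' event-of-interest time), runs the requested tests on the shared data
#' (paired comparison), and tabulates rejections at level \code{alpha}.
#'
#' @param config a \code{"cr_config"}.
#' @param methods subset of \code{c("diff", "sdiff")}.
#' @param reps number of replications.
#' @param alpha nominal significance level.
#' @param seed optional integer seed (set once for the whole study).
#' @param rho working correlation for the supremum test.
#' @param store_p keep the per-replicate p-values (matrix \code{p_values}
#'   in the result), e.g. for null-uniformity diagnostics.
#' @return A \code{"cr_rejection"} object: data frame of per-method
#'   rejection rates with binomial Monte-Carlo standard errors, plus
#'   \code{reps}, \code{alpha}, and the count of degenerate replicates.
#' @export
rejection_study <- function(config, methods = c("diff", "sdiff"),
                            reps = 1000, alpha = 0.05, seed = NULL,
                            rho = 0.5, store_p = FALSE) {
  methods <- match.arg(methods, c("diff", "sdiff"), several.ok = TRUE)
  if (reps < 1) stop("'reps' must be positive")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pm <- matrix(NA_real_, nrow = reps, ncol = 2,
               dimnames = list(NULL, c("diff", "sdiff")))
  for (i in seq_len(reps)) {
    a <- sample_group(config, 1)
    b <- sample_group(config, 2)
    pm[i, ] <- .fast_tests(a$time, a$status, b$time, b$status, rho = rho)
  }
  ok <- stats::complete.cases(pm)
  rates <- colMeans(pm[ok, methods, drop = FALSE] <= alpha)
  res <- data.frame(method = methods, rate = rates,
                    se = sqrt(rates * (1 - rates) / sum(ok)),
                    row.names = NULL)
  structure(list(results = res, reps = reps, used = sum(ok),
                 alpha = alpha, scenario = config$scenario,
                 n1 = config$n1, n2 = config$n2,
                 censoring = config$censoring,
                 p_values = if (store_p) pm[, methods, drop = FALSE]),
            class = "cr_rejection")
}

#' Observed power at a supplied total sample size
#'
#' Rejection rate of one test under the configuration's alternative when the
#' study is run at \code{n_total} subjects split in the configuration's
#' allocation ratio; the companion of the sample-size formulas for
#' calibration checks.
#'
#' @inheritParams rejection_study
#' @param method "diff" or "sdiff".
#' @param n_total total sample size.
#' @return The observed rejection rate (a single number) with attribute
#'   \code{"se"}.
#' @export
observed_power_at_n <- function(config, method = c("diff", "sdiff"),
                                n_total, reps = 1000, alpha = 0.05,
                                seed = NULL) {
  method <- match.arg(method)
  r <- config$n2 / config$n1
  cfg <- config
  cfg$n1 <- max(1L, round(n_total / (1 + r)))
  cfg$n2 <- as.integer(n_total) - cfg$n1
  rs <- rejection_study(cfg, methods = method, reps = reps, alpha = alpha,
                        seed = seed)
  out <- rs$results$rate[1]
  attr(out, "se") <- rs$results$se[1]
  out
}

#' @export
print.cr_rejection <- function(x, ...) {
  cat(sprintf(
    "Rejection study: scenario %s, n = %d/%d, censoring %.0f%%, %d reps (alpha = %g)\n",
    x$scenario, x$n1, x$n2, 100 * x$censoring, x$reps, x$alpha))
  if (x$used < x$reps)
    cat("  (", x$reps - x$used, "degenerate replicates dropped )\n")
  for (i in seq_len(nrow(x$results)))
    cat(sprintf("  %-6s rate = %.4f (MC se %.4f)\n", x$results$method[i],
                x$results$rate[i], x$results$se[i]))
  invisible(x)
}

#' @export
print.cr_config <- function(x, ...) {
  cat(sprintf("Simulation config: scenario %s, n = %d/%d, censoring %.0f%%",
              x$scenario, x$n1, x$n2, 100 * x$censoring))
  if (!is.null(x$censor_upper))
    cat(sprintf(" (C ~ U(0, %.3g))", x$censor_upper))
  cat("\n")
  invisible(x)
}
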