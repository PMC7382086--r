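## Counting-process kernel shared by the Kaplan-Meier and Aalen-Johansen
## estimators.  Everything downstream (RMTL, the two-sample tests, sigma of
## the supremum statistic) evaluates these step functions on its own grid, so
## the kernel returns cumulative quantities on the distinct observed times.

# Tie convention: subjects sharing a time contribute to the same d_ij;
# censorings at an event time are processed after the events (they stay in
# the risk set n_i for that time).
.cr_core <- function(time, status, cause = 1L) {
  o <- order(time)
  tt <- time[o]
  ss <- status[o]
  n <- length(tt)
  ut <- unique(tt)
  K <- length(ut)
  idx <- findInterval(tt, ut)            # tt sorted, ut = unique(tt)
  cnt <- tabulate(idx, nbins = K)        # subjects leaving at each ut
  n_risk <- n - c(0, cumsum(cnt))[seq_len(K)]
  d_cause <- tabulate(idx[ss == cause], nbins = K)
  d_all <- tabulate(idx[ss != 0L], nbins = K)
  surv <- cumprod(1 - d_all / n_risk)
  surv_prev <- c(1, surv[-K])            # S-hat(t_{i-1}), left-hand limit
  inc <- d_cause / n_risk * surv_prev
  cif <- cumsum(inc)

  # Aalen/delta-method variance of the cumulative incidence (the standard
  # counting-process estimator):
  #   V[I(t)] = sum_{k<=t} { [I(t)-I(t_k)]^2 d_k/(n_k(n_k-d_k))
  #             + S(t_{k-1})^2 (n_k-d_{ck}) d_{ck} / n_k^3
  #             - 2 [I(t)-I(t_k)] S(t_{k-1}) d_{ck} / n_k^2 }
  # expanded in I(t) so that V(t) = I(t)^2 A - 2 I(t) B + C with cumulative
  # coefficients A, B, C.  Terms with n_k = d_k (risk set exhausted) vanish
  # because no later time exists; they are zeroed to avoid 0/0.
  g <- ifelse(n_risk > d_all, d_all / (n_risk * (n_risk - d_all)), 0)
  h <- d_cause / n_risk^2 * surv_prev
  A <- cumsum(g)
  B <- cumsum(cif * g + h)
  C <- cumsum(cif^2 * g + surv_prev^2 * (n_risk - d_cause) * d_cause /
                n_risk^3 + 2 * cif * h)
  var_cif <- pmax(cif^2 * A - 2 * cif * B + C, 0)

  list(time = ut, n_risk = n_risk, d_cause = d_cause, d_all = d_all,
       surv = surv, surv_prev = surv_prev, cif = cif, var_cif = var_cif,
       var_coef = list(A = A, B = B, C = C), n = n, cause = cause)
}

# Evaluate a right-continuous step function given by (knots, values),
# value 'left' before the first knot.
.step_at <- function(knots, values, t, left) {
  i <- findInterval(t, knots)
  out <- rep_len(left, length(t))
  out[i > 0] <- values[i[i > 0]]
  out
}

# Aalen variance of the CIF evaluated at arbitrary times (the coefficients
# and I(t) are step functions on the same knots).
.cif_var_at <- function(core, t) {
  i <- findInterval(t, core$time)
  out <- numeric(length(t))
  pos <- i > 0
  if (any(pos)) {
    j <- i[pos]
    I <- core$cif[j]
    out[pos] <- pmax(I^2 * core$var_coef$A[j] - 2 * I * core$var_coef$B[j] +
                       core$var_coef$C[j], 0)
  }
  out
}

#' All-cause (event-free) survival curve
#'
#' Kaplan-Meier estimate of the probability of being free of any event,
#' treating every nonzero cause code as an event and code 0 as censoring.
#'
#' @param sample a one-group \code{"cr_sample"} (a two-group sample is
#'   refused; use [split_groups()]).
#' @return An object of class \code{"cr_surv"}: a list with \code{time}
#'   (distinct observed times), \code{surv} (right-continuous step values),
#'   \code{n_risk}, \code{n_event} and \code{n}.
#' @examples
#' s <- cr_sample(c(1, 2, 3, 4), c(1, 2, 1, 0))
#' allcause_survival(s)
#' @export
allcause_survival <- function(sample) {
  stopifnot(inherits(sample, "cr_sample"))
  if (!is.null(sample$group))
    stop("one-group sample expected; use split_groups() first")
  core <- .cr_core(sample$time, sample$status)
  structure(list(time = core$time, surv = core$surv, n_risk = core$n_risk,
                 n_event = core$d_all, n = core$n),
            class = "cr_surv")
}

#' Cumulative incidence function of one cause
#'
#' Aalen-Johansen estimate \eqn{\hat I_j(t) = \sum_{t_i \le t}
#' (d_{ij}/n_i)\,\hat S(t_{i-1})}, where \eqn{\hat S} is the all-cause
#' Kaplan-Meier estimate, together with the pointwise counting-process
#' (Aalen) variance.  Right-continuous; 0 before the first event time.
#'
#' @param sample a one-group \code{"cr_sample"}.
#' @param cause integer cause code, 1 (event of interest) or 2 (competing
#'   event); larger codes are allowed when present in the data.
#' @return An object of class \code{"cr_cif"}: list with \code{time}
#'   (distinct observed times), \code{cif}, \code{var} (pointwise variance of
#'   \eqn{\hat I_j}), \code{n_risk}, \code{n_event} (events of this cause),
#'   \code{cause} and \code{n}; the counting-process coefficients needed to
#'   evaluate the variance on arbitrary grids are kept internally.
#' @examples
#' s <- cr_sample(c(1, 2, 3, 4), c(1, 2, 1, 0))
#' cif(s, cause = 1)
#' @export
cif <- function(sample, cause = 1L) {
  stopifnot(inherits(sample, "cr_sample"))
  if (!is.null(sample$group))
    stop("one-group sample expected; use split_groups() first")
  cause <- as.integer(cause)
  if (cause < 1L) stop("'cause' must be a positive event code")
  core <- .cr_core(sample$time, sample$status, cause = cause)
  structure(list(time = core$time, cif = core$cif, var = core$var_cif,
                 n_risk = core$n_risk, n_event = core$d_cause,
                 cause = cause, n = core$n, core = core),
            class = "cr_cif")
}

#' Evaluate a survival or cumulative incidence curve
#'
#' Right-continuous step-function evaluation; before the first observed time
#' the survival curve is 1 and the CIF is 0.
#'
#' @param x a \code{"cr_surv"} or \code{"cr_cif"} object.
#' @param t numeric vector of evaluation times.
#' @return Numeric vector of curve values at \code{t}.
#' @export
curve_at <- function(x, t) {
  if (inherits(x, "cr_surv")) return(.step_at(x$time, x$surv, t, 1))
  if (inherits(x, "cr_cif")) return(.step_at(x$time, x$cif, t, 0))
  stop("unsupported object")
}

#' Pointwise variance of a cumulative incidence curve
#' @param x a \code{"cr_cif"} object.
#' @param t numeric vector of evaluation times.
#' @return Aalen variance of \eqn{\hat I_j(t)} at each \code{t} (0 before the
#'   first observed time).
#' @export
cif_var_at <- function(x, t) {
  stopifnot(inherits(x, "cr_cif"))
  .cif_var_at(x$core, t)
}

#' @export
print.cr_surv <- function(x, ...) {
  cat("All-cause Kaplan-Meier curve: n =", x$n, "\n")
  cat("  ", length(x$time), "distinct times; S(last) =",
      format(x$surv[length(x$surv)], digits = 4), "\n")
  invisible(x)
}

#' @export
print.cr_cif <- function(x, ...) {
  cat("Cumulative incidence, cause", x$cause, ": n =", x$n, "\n")
  k <- length(x$time)
  cat("  ", sum(x$n_event), "events;", "I(last) =",
      format(x$cif[k], digits = 4),
      "(se", format(sqrt(x$var[k]), digits = 3), ")\n")
  invisible(x)
}
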