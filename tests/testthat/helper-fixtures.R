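# Hand-checkable four-subject sample: events of interest at t = 1 and 3,
# competing event at t = 2, censoring at t = 4.  All downstream step-function
# quantities are exact rationals:
#   S-hat            = 3/4, 1/2, 1/4, 1/4
#   I1-hat(1), I1(3) = 1/4, 1/2        I2-hat(2) = 1/4
#   RMTL1(4) = 1     RMTL2(4) = 1/2    RMSTc(4) = 5/2
toy_sample <- function() cr_sample(c(1, 2, 3, 4), c(1, 2, 1, 0))

# second toy group used for two-sample hand computations
toy_sample_b <- function() cr_sample(c(1.5, 2.5, 3.5, 4.5), c(1, 1, 2, 0))

toy_two_group <- function() bind_groups(toy_sample(), toy_sample_b(),
                                        labels = c("a", "b"))

# random competing-risks sample with optional censoring, for property loops
random_sample <- function(n, cens = 0) {
  tt <- rweibull(n, shape = 1.3, scale = 10)
  cause <- ifelse(runif(n) < 0.7, 1L, 2L)
  if (cens > 0) {
    cc <- runif(n, 0, quantile(tt, 0.95) / cens)
    cens_i <- cc < tt
    tt <- pmin(tt, cc)
    cause[cens_i] <- 0L
  }
  cr_sample(tt, cause)
}

# direct evaluation of the cumulative-difference grid sum, kept deliberately
# naive (explicit loop over the pooled grid) as an oracle for sdiff_cumdiff
naive_cumdiff <- function(sa, sb, tau) {
  ca <- cif(sa)
  cb <- cif(sb)
  ev <- sort(unique(c(sa$time[sa$status != 0], sb$time[sb$status != 0])))
  ev <- ev[ev <= tau]
  g <- if (max(ev) < tau) c(ev, tau) else ev
  out <- numeric(length(g) - 1)
  acc <- 0
  for (i in seq_len(length(g) - 1)) {
    acc <- acc + (curve_at(cb, g[i]) - curve_at(ca, g[i])) * (g[i + 1] - g[i])
    out[i] <- acc
  }
  data.frame(time = g[seq_len(length(g) - 1)], delta = out)
}

# naive double-sum evaluation of sigma^2(tau), the oracle for sdiff_sigma
naive_sigma <- function(sa, sb, tau, rho) {
  ca <- cif(sa)
  cb <- cif(sb)
  ev <- sort(unique(c(sa$time[sa$status != 0], sb$time[sb$status != 0])))
  ev <- ev[ev <= tau]
  g <- if (max(ev) < tau) c(ev, tau) else ev
  K <- length(g) - 1
  w <- diff(g)
  V <- cif_var_at(cb, g[seq_len(K)]) + cif_var_at(ca, g[seq_len(K)])
  s2 <- 0
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      r <- if (i == j) 1 else rho
      s2 <- s2 + r * w[i] * w[j] * sqrt(V[i] * V[j])
    }
  }
  sqrt(s2)
}
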