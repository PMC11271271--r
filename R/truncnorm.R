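## Truncated-normal helpers for amplitude distributions.
##
## Event amplitudes are reported in the literature as mean +/- SD over
## *classified* events, i.e. over a class band such as [0.2, 3) mV for
## unitary EPSPs.  The generator therefore draws from a normal truncated to
## the class band, with the location parameter calibrated so that the
## realized (truncated) mean equals the requested class mean.

## Mean of N(mu, sd) truncated to [lo, hi].
tnorm_mean <- function(mu, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

## Location parameter mu such that the truncated mean equals `target`.
calibrate_tnorm_mu <- function(target, sd, lo = -Inf, hi = Inf) {
  if (!is.finite(lo) && !is.finite(hi)) return(target)
  f <- function(mu) tnorm_mean(mu, sd, lo, hi) - target
  ## expand the bracket stepwise; far tails are numerically unreliable
  lo_b <- target - sd; hi_b <- target + sd
  for (k in seq_len(20)) {
    flo <- f(lo_b); fhi <- f(hi_b)
    if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0) {
      return(stats::uniroot(f, lower = lo_b, upper = hi_b, tol = 1e-10)$root)
    }
    if (!is.finite(flo) || flo >= 0) lo_b <- lo_b - sd else hi_b <- hi_b + sd
  }
  stop("could not calibrate truncated-normal location for target ", target,
       call. = FALSE)
}

## Inverse-CDF sampler for N(mu, sd) truncated to [lo, hi].
rtnorm <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  plo <- pnorm(lo, mu, sd)
  phi <- pnorm(hi, mu, sd)
  qnorm(runif(n, plo, phi), mu, sd)
}
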