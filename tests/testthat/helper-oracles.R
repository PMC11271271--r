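## Independent oracles used across the suite.

## Exact two-sided Mann-Whitney p by enumerating all rank assignments.
mwu_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

## Brute-force co-activity edge set: all pairs x all bins.
coactivity_brute <- function(trains, duration_s, bin_width_s) {
  ids <- vapply(trains, function(tr) tr$channel, numeric(1))
  bins <- lapply(trains, function(tr) {
    st <- tr$spike_times_s
    st <- st[st >= 0 & st < duration_s]
    unique(floor(st / bin_width_s))
  })
  edges <- NULL
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && length(intersect(bins[[i]], bins[[j]]))) {
      edges <- rbind(edges, sort(c(ids[i], ids[j])))
    }
  }
  edges
}

## Exhaustive CMA computation on a constructed ISI histogram.
cma_brute <- function(h, alpha) {
  cma <- cumsum(h) / seq_along(h)
  m <- which.max(cma)
  after <- which(cma < alpha * max(cma) & seq_along(cma) > m)[1L]
  if (is.na(after)) length(h) else after
}

## Simple Poisson spike train helper.
poisson_train <- function(channel, rate, duration, seed) {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  list(channel = channel, spike_times_s = sort(runif(n, 0, duration)))
}
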