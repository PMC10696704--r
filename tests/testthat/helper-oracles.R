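# Independent step-by-step oracle for the assimilation-rate chain: written
# as plain arithmetic, never calling the package's isotope functions.
oracleRate <- function(delta0, deltaT, poc0, pocT, t, ca, cs) {
  vpdb <- 0.0112372
  r0 <- (delta0 / 1000 + 1) * vpdb
  rt <- (deltaT / 1000 + 1) * vpdb
  n0 <- r0 / (r0 + 1)
  nt <- rt / (rt + 1)
  (pocT * nt - poc0 * n0) / t * (ca + cs) / cs
}

# Brute-force best contiguous run of length k over positions `idx` (indices
# into `copies` that lie in the window), ties broken toward later (heavier)
# runs. Enumerates every candidate run.
oracleSelect <- function(copies, idx, k) {
  best <- NULL; bestSum <- -Inf
  for (s in seq_len(length(idx))) {
    e <- s + k - 1
    if (e > length(idx)) break
    run <- idx[s:e]
    if (any(diff(run) != 1)) next
    tot <- sum(copies[run])
    if (tot >= bestSum) { bestSum <- tot; best <- run }
  }
  list(run = best, sum = bestSum)
}

# random gradient profile over sorted densities
randomProfile <- function(n, seed) {
  withr::with_seed(seed, {
    d <- sort(runif(n, 1.685, 1.765))
    while (anyDuplicated(d)) d <- sort(runif(n, 1.685, 1.765))
    gradientProfile("rnd", density = d, copies = runif(n, 0, 1000))
  })
}
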