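# Independent oracles, deliberately naive and separate from the package's
# code paths.

# umbrella statistic by quadruple loop over chain pairs
naive_umbrella_stat <- function(groups, pattern) {
  s <- 0
  rc <- pattern$rising_chain
  if (length(rc) >= 2)
    for (i in 1:(length(rc) - 1)) for (j in (i + 1):length(rc))
      for (x in groups[[rc[i]]]) for (y in groups[[rc[j]]])
        s <- s + (x < y) + 0.5 * (x == y)
  fc <- pattern$falling_chain
  if (length(fc) >= 2)
    for (i in 1:(length(fc) - 1)) for (j in (i + 1):length(fc))
      for (x in groups[[fc[i]]]) for (y in groups[[fc[j]]])
        s <- s + (x > y) + 0.5 * (x == y)
  s
}

# all permutations of 1..n, list of integer vectors
naive_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in naive_perms(n - 1)) for (k in 0:(n - 1))
    out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

# exact permutation p by full enumeration
naive_exhaustive_p <- function(groups, pattern) {
  vals <- unlist(groups)
  sizes <- lengths(groups)
  obs <- naive_umbrella_stat(groups, pattern)
  idx <- rep(seq_along(sizes), sizes)
  hits <- 0L; total <- 0L
  for (p in naive_perms(length(vals))) {
    g <- split(vals[p], idx)
    total <- total + 1L
    if (naive_umbrella_stat(g, pattern) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# one-sided Fisher p by hypergeometric enumeration with choose()
naive_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(m, k)
  pr <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  sum(pr[xs >= a])
}

# BH step-up written directly from the definition
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, m / i * p[o[i]])
    adj[o[i]] <- cur
  }
  adj
}

# 4th central moment of NB(mu, size) by direct summation, for the
# standard error of a sample variance
nb_moment4 <- function(mu, size) {
  kmax <- qnbinom(1 - 1e-13, size = size, mu = mu)
  k <- 0:kmax
  pr <- dnbinom(k, size = size, mu = mu)
  sum((k - mu)^4 * pr)
}
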