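# Independent brute-force oracles. These deliberately avoid the package's
# formulas: the Mann-Whitney oracle counts pairwise wins, the Fisher
# oracle sums binomial-coefficient ratios, the outlier oracle loops over
# explicit label assignments.

# U statistic by pairwise comparison counting (not rank sums)
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-tailed Mann-Whitney p by enumerating every group assignment
oracle_mwu_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  mu <- n * m / 2
  d_obs <- abs(oracle_u(x, y) - mu)
  cmb <- combn(n + m, n)
  hits <- 0
  for (j in seq_len(ncol(cmb))) {
    xx <- pooled[cmb[, j]]
    yy <- pooled[-cmb[, j]]
    if (abs(oracle_u(xx, yy) - mu) >= d_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(cmb)
}

# two-sided Fisher p: hypergeometric point probabilities from choose()
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  prob <- sapply(supp, function(i) {
    choose(m, i) * choose(n, k - i) / choose(m + n, k)
  })
  obs <- prob[supp == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# one-sided (upper tail) over-representation p
oracle_ora_p <- function(overlap, set_size, query_size, universe_size) {
  supp <- overlap:min(set_size, query_size)
  sum(sapply(supp, function(i) {
    choose(set_size, i) * choose(universe_size - set_size, query_size - i) /
      choose(universe_size, query_size)
  }))
}

# naive O(n^2) step-up BH
oracle_bh <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- sapply(seq_len(n), function(j) {
      rank_j <- sum(p <= p[j])
      n * p[j] / rank_j
    })
    adj[i] <- min(1, min(cand[p >= p[i]]))
  }
  adj
}

# range-exceedance statistic via explicit loops
oracle_outlier_stat <- function(nv, rv, exponent = 1) {
  lo <- min(nv); hi <- max(nv)
  s_dn <- 0; s_up <- 0
  for (v in rv) {
    if (v < lo) s_dn <- s_dn + (lo - v)^exponent
    if (v > hi) s_up <- s_up + (v - hi)^exponent
  }
  if (s_up >= s_dn) s_up else -s_dn
}

oracle_outlier_p <- function(nv, rv, exponent = 1) {
  v <- c(nv, rv)
  m <- length(rv); N <- length(v)
  s_obs <- abs(oracle_outlier_stat(nv, rv, exponent))
  cmb <- combn(N, m)
  hits <- 0
  for (j in seq_len(ncol(cmb))) {
    idx <- cmb[, j]
    if (abs(oracle_outlier_stat(v[-idx], v[idx], exponent)) >=
        s_obs - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / ncol(cmb)
}

oracle_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- 0
  for (g in a) if (any(b == g)) both <- both + 1
  c(length(a) - both, length(b) - both, both)
}
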