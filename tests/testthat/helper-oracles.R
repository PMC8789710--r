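# test-side enumeration oracles, written against the raw definitions

# exact signed-rank p by bitmask enumeration over sign assignments
oracleWilcoxonP <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    pos <- bitwAnd(m, 2^(0:(n - 1))) > 0
    ws[m + 1] <- sum(r[pos])
  }
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# exact Mann-Whitney p; U computed by direct pair counting (not rank sums)
oracleMannWhitneyP <- function(a, b) {
  uOf <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y)
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  u_obs <- uOf(a, b)
  pool <- c(a, b)
  na <- length(a)
  sel <- utils::combn(length(pool), na)
  us <- apply(sel, 2, function(ix) uOf(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# tau-b by explicit pair loop
oracleTauB <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- choose(n, 2)
  n1 <- sum(choose(table(x), 2)); n2 <- sum(choose(table(y), 2))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}
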