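# Independent brute-force oracles. These are deliberately written as plain
# scalar loops over the published formulas, separate from the package's
# vectorized implementations.

rand_hapmat <- function(n, S, seed, pop = "pop1") {
  set.seed(seed)
  m <- matrix(rbinom(n * S, 1L, runif(S, 0.1, 0.9)[rep(seq_len(S),
                                                       each = n)]),
              nrow = n)
  for (j in seq_len(S)) {       # force every site polymorphic
    if (sum(m[, j]) == 0L) m[sample.int(n, 1L), j] <- 1L
    if (sum(m[, j]) == n) m[sample.int(n, 1L), j] <- 0L
  }
  pos <- sort(sample.int(100000L, S))
  sm <- data.frame(haplotype = seq_len(n),
                   sample = rep(sprintf("s%02d", seq_len(n / 2)), each = 2),
                   population = pop)
  haplotype_matrix(m, pos, sm)
}

oracle_pi <- function(m) {
  n <- nrow(m); tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2)
}

oracle_theta_w <- function(m) {
  n <- nrow(m)
  S <- 0
  for (j in seq_len(ncol(m))) {
    cj <- sum(m[, j])
    if (cj > 0 && cj < n) S <- S + 1
  }
  a <- 0
  for (i in 1:(n - 1)) a <- a + 1 / i
  S / a
}

oracle_tajd <- function(m) {
  n <- nrow(m)
  S <- sum(apply(m, 2, function(x) sum(x) > 0 && sum(x) < n))
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (oracle_pi(m) - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# unfolded-spectrum (xi) evaluation of the normalized Fay-Wu statistic
oracle_dh <- function(m) {
  n <- nrow(m)
  xi <- rep(0, n - 1)
  for (j in seq_len(ncol(m))) {
    cj <- sum(m[, j])
    if (cj > 0 && cj < n) xi[cj] <- xi[cj] + 1
  }
  S <- sum(xi)
  if (S == 0) return(NA_real_)
  pi <- 0; tl <- 0
  for (i in 1:(n - 1)) {
    pi <- pi + 2 * i * (n - i) * xi[i] / (n * (n - 1))
    tl <- tl + i * xi[i] / (n - 1)
  }
  an <- sum(1 / (1:(n - 1))); bn <- sum(1 / (1:(n - 1))^2)
  bn1 <- bn + 1 / n^2
  tw <- S / an; t2 <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * tw +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * t2
  (pi - tl) / sqrt(v)
}

oracle_fst <- function(nA, pA, hA, nB, pB, hB) {
  nbar <- (nA + nB) / 2
  nC <- (2 * nbar - (nA^2 + nB^2) / (2 * nbar)) / 1
  pbar <- (nA * pA + nB * pB) / (2 * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / nbar
  hbar <- (nA * hA + nB * hB) / (2 * nbar)
  a <- (nbar / nC) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

oracle_dind <- function(m, focal, flanks) {
  der <- which(m[, focal] == 1); anc <- which(m[, focal] == 0)
  mp <- function(rows) {
    tot <- 0; np <- 0
    for (i in seq_along(rows)[-length(rows)])
      for (j in (i + 1):length(rows)) {
        tot <- tot + sum(m[rows[i], flanks] != m[rows[j], flanks])
        np <- np + 1
      }
    tot / np
  }
  c(i_pi_A = mp(anc), i_pi_D = mp(der))
}

oracle_r2 <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / n; pB <- (nAB + naB) / n
  D <- nAB / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# add-one midpoint rank (the package's declared estimator), counted naively
oracle_rank <- function(values, x) {
  nl <- 0; nt <- 0
  for (v in values) {
    if (v < x) nl <- nl + 1
    if (v == x) nt <- nt + 1
  }
  (nl + (nt + 1) / 2) / (length(values) + 1)
}
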