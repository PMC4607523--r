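# Core statistics against trivial identities and brute-force oracles.

simple_hm <- function(m, pos = NULL) {
  n <- nrow(m)
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 100L
  sm <- data.frame(haplotype = seq_len(n),
                   sample = rep(sprintf("s%02d", seq_len(n / 2)), each = 2),
                   population = "pop1")
  haplotype_matrix(m, pos, sm)
}

test_that("pi and theta_W identities hold", {
  m0 <- matrix(rep(c(1L, 0L, 1L, 0L), each = 5), nrow = 5)  # 5 identical
  expect_equal(nucleotide_diversity(m0), 0)
  m2 <- rbind(c(0L, 0L, 1L, 0L, 1L), c(1L, 0L, 0L, 1L, 1L))
  expect_equal(nucleotide_diversity(m2), 3)        # one pair, 3 diffs
  expect_equal(watterson_theta(m2), 3)             # a_2 = 1
  expect_equal(watterson_theta(matrix(0L, 2, 4)), 0)
  m4 <- matrix(0L, nrow = 4, ncol = 6)
  m4[1, ] <- 1L                                    # 6 segregating sites
  expect_equal(watterson_theta(m4), 6 / (1 + 1 / 2 + 1 / 3))
  expect_error(nucleotide_diversity(matrix(0L, 1, 3)), "2 haplotypes")
})

test_that("Tajima's D is 0 for n = 2 and undefined for S = 0", {
  for (seed in 1:5) {
    m <- rand_hapmat(2, 10, seed)$alleles
    expect_equal(tajimas_d(m), 0)
  }
  expect_true(is.na(tajimas_d(matrix(0L, 6, 4))))
})

test_that("statistics match brute-force oracles on 100 random matrices", {
  for (k in 1:100) {
    n <- 2L * sample(3:6, 1)
    S <- sample(10:50, 1)
    hm <- rand_hapmat(n, S, seed = 1000 + k)
    m <- hm$alleles
    expect_equal(nucleotide_diversity(hm), oracle_pi(m), tolerance = 1e-10)
    expect_equal(watterson_theta(hm), oracle_theta_w(m), tolerance = 1e-10)
    expect_equal(tajimas_d(hm), oracle_tajd(m), tolerance = 1e-10)
    expect_equal(fay_wu_dh(hm), oracle_dh(m), tolerance = 1e-10)
  }
})

test_that("row permutation changes no statistic", {
  hm <- rand_hapmat(10, 30, seed = 7)
  set.seed(8)
  perm <- sample.int(10)
  hp <- hm
  hp$alleles <- hm$alleles[perm, ]
  for (f in list(nucleotide_diversity, watterson_theta, tajimas_d,
                 fay_wu_dh))
    expect_equal(f(hp), f(hm))
})

test_that("DH excludes unpolarized sites with a warning", {
  hm <- rand_hapmat(6, 12, seed = 3)
  hm$polarized[1:4] <- FALSE
  expect_warning(v <- fay_wu_dh(hm), "unpolarized")
  expect_equal(v, fay_wu_dh(hm, site_subset = 5:12))
  hm$polarized[] <- FALSE
  expect_warning(v0 <- fay_wu_dh(hm), "unpolarized")
  expect_true(is.na(v0))
})

test_that("sliding windows tile the region as specified", {
  hm <- rand_hapmat(8, 40, seed = 11)
  hm$positions <- sort(sample.int(10000L, 40))
  hm$region <- c(1L, 10000L)
  w <- sliding_dh(hm, window = 5000, step = 500)
  expect_equal(nrow(w), 11)                         # (10000-5000)/500 + 1
  expect_equal(w$start[1], 1)
  expect_equal(w$end[11], 10000)
  # a window with no SNPs is undefined
  hm2 <- hm; hm2$positions <- sort(sample(7000:10000, 40));
  hm2$region <- c(1L, 10000L)
  w2 <- sliding_dh(hm2, window = 5000, step = 500)
  expect_false(w2$defined[1])
  expect_true(is.na(w2$value[1]))
  # window spanning everything equals the whole-matrix DH
  w3 <- sliding_dh(hm, window = 20000, step = 500)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$value, fay_wu_dh(hm))
  expect_error(sliding_dh(hm, window = 100, step = 200), "window >= step")
})

test_that("Weir-Cockerham FST matches identities and the formula oracle", {
  # fixed difference, no heterozygotes
  expect_equal(weir_cockerham_fst(list(n = 10, p = 0, het = 0),
                                  list(n = 10, p = 1, het = 0)), 1)
  # identical frequencies under Hardy-Weinberg: estimate <= 0
  expect_lte(weir_cockerham_fst(list(n = 20, p = 0.4, het = 2 * .4 * .6),
                                list(n = 20, p = 0.4, het = 2 * .4 * .6)), 0)
  # printed toy counts against the independent evaluation
  expect_equal(weir_cockerham_fst(list(n = 10, p = 0.3, het = 0.42),
                                  list(n = 10, p = 0.7, het = 0.42)),
               oracle_fst(10, 0.3, 0.42, 10, 0.7, 0.42), tolerance = 1e-10)
  # random parameter draws
  set.seed(21)
  for (k in 1:25) {
    nA <- sample(5:30, 1); nB <- sample(5:30, 1)
    pA <- runif(1, 0.05, 0.95); pB <- runif(1, 0.05, 0.95)
    hA <- runif(1, 0, 2 * pA * (1 - pA)); hB <- runif(1, 0, 2 * pB * (1 - pB))
    expect_equal(weir_cockerham_fst(list(n = nA, p = pA, het = hA),
                                    list(n = nB, p = pB, het = hB)),
                 oracle_fst(nA, pA, hA, nB, pB, hB), tolerance = 1e-10)
  }
  # monomorphic across both populations -> undefined
  expect_true(is.na(weir_cockerham_fst(list(n = 10, p = 0, het = 0),
                                       list(n = 8, p = 0, het = 0))))
})

test_that("per-site FST wrapper agrees with the scalar estimator", {
  hm <- rand_hapmat(24, 20, seed = 31)
  hm$sample_map$population <- rep(c("A", "B"), each = 12)
  tab <- sweepscan:::.fst_pair_table(hm, "A", "B")
  for (s in c(1, 5, 20))
    expect_equal(fst_site(hm, s, "A", "B"), tab$fst[s], tolerance = 1e-12)
})

test_that("DIND matches the within-class brute-force oracle", {
  for (k in 1:10) {
    hm <- rand_hapmat(8, 45, seed = 500 + k)
    focal <- 23L
    r <- dind(hm, focal)
    if (!r$computed) next
    flanks <- sweepscan:::.select_flanks(
      setdiff(polymorphic_sites(hm), focal), focal, 40L)
    o <- oracle_dind(hm$alleles, focal, flanks)
    expect_equal(r$i_pi_A, unname(o["i_pi_A"]), tolerance = 1e-10)
    expect_equal(r$i_pi_D, unname(o["i_pi_D"]), tolerance = 1e-10)
    if (!r$sentinel)
      expect_equal(r$dind, unname(o["i_pi_A"] / o["i_pi_D"]),
                   tolerance = 1e-10)
  }
})

test_that("DIND class degeneracies behave as specified", {
  hm <- rand_hapmat(8, 90, seed = 99)
  focal <- 45L
  m <- hm$alleles
  der <- which(m[, focal] == 1)
  # identical derived-class haplotypes over the flanks -> sentinel
  m[der, -focal] <- rep(m[der[1], -focal], each = length(der))
  hs <- simple_hm(m, hm$positions)
  r <- dind(hs, focal)
  expect_true(r$sentinel)
  expect_true(is.na(r$dind))
  # identical ancestral class, diverse derived -> dind = 0
  m2 <- hm$alleles
  anc <- which(m2[, focal] == 0)
  m2[anc, -focal] <- rep(m2[anc[1], -focal], each = length(anc))
  r2 <- dind(simple_hm(m2, hm$positions), focal)
  expect_equal(r2$dind, 0)
  # fewer than 40 flanking variants -> not computed
  r3 <- dind(rand_hapmat(8, 30, seed = 100), 15L)
  expect_false(r3$computed)
  # unbalanced edge: focal near the start borrows from the right
  r4 <- dind(hm, 3L)
  expect_equal(r4$n_flank_used, 40L)
})

test_that("sentinel finalization applies the dataset max + 20 rule", {
  df <- data.frame(site = 1:4, pos = 1:4, daf = .5,
                   i_pi_A = 1, i_pi_D = c(1, 1, 0, 0),
                   dind = c(1.2, 3.4, NA, NA),
                   sentinel = c(FALSE, FALSE, TRUE, TRUE),
                   computed = TRUE, n_flank_used = 40L)
  out <- finalize_dind_sentinels(df)
  expect_equal(out$dind[3:4], c(23.4, 23.4))
  expect_identical(finalize_dind_sentinels(df[1:2, ]), df[1:2, ])
  df2 <- df[c(1, 3), ]; df2$dind[1] <- 0
  expect_equal(finalize_dind_sentinels(df2)$dind[2], 20)
  df3 <- df[3:4, ]
  expect_error(finalize_dind_sentinels(df3), "sentinel")
})

test_that("r2 matches direct enumeration", {
  x <- c(rep(1L, 5), rep(0L, 5))
  expect_equal(ld_r2(x, x), 1)
  expect_true(is.na(ld_r2(x, rep(0L, 10))))
  # AB = 4, Ab = 1, aB = 1, ab = 4
  a <- c(rep(1L, 5), rep(0L, 5))
  b <- c(rep(1L, 4), 0L, 1L, rep(0L, 4))
  expect_equal(ld_r2(a, b), oracle_r2(4, 1, 1, 4), tolerance = 1e-12)
})

test_that("missing data uses rescaled mutually non-missing comparisons", {
  m <- rbind(c(0L, 1L, NA, 1L), c(1L, 1L, 0L, 0L))
  # 2 diffs over 3 compared sites, rescaled to 4 sites: 2 * 4/3
  expect_equal(nucleotide_diversity(m), 2 * 4 / 3)
})
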