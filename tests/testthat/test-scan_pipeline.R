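# Region definition, decision rules, published-evidence reproduction,
# resampling significance and report export.

test_that("scan regions apply symmetric clipped flanks", {
  r <- define_region("g", "chr1", 100000, 110000)
  expect_equal(c(r$scan_start, r$scan_end), c(75000L, 135000L))
  r2 <- define_region("g", "chr1", 10000, 15000)
  expect_equal(r2$scan_start, 1L)
  r3 <- define_region("g", "chr1", 50000, 60000)
  expect_equal(r3$scan_end - r3$scan_start,
               (60000 - 50000) + 2 * 25000)
  expect_error(define_region("g", "chr1", 10, 5), "gene_end")
})

toy_evidence <- function(dind = NULL, fst = NULL, gs = NULL)
  list(gene = "toy", gene_stats = gs, dind = dind, fst = fst)

pops3 <- c("YRI", "CEU", "CHBJPT")

test_that("classification rules R1-R3 fire as specified", {
  # R2: one SNP significant in all three populations
  ev <- toy_evidence(dind = data.frame(
    snp = "s1", population = pops3, rank = c(0.98, 0.97, 0.99)))
  cl <- classify_targets(ev, populations = pops3)
  expect_true(cl$flagged)
  expect_true("R2" %in% cl$rules)
  # R1 via families B + C: two CEU variants with DIND and FST outliers
  ev2 <- toy_evidence(
    dind = data.frame(snp = c("a", "b"), population = "CEU",
                      rank = c(0.95, 0.96)),
    fst = data.frame(snp = c("a", "b"), pair = "YRI/CEU", rank = 0.99))
  cl2 <- classify_targets(ev2, populations = pops3)
  expect_true(cl2$flagged)
  expect_true("R1" %in% cl2$rules)
  expect_equal(cl2$r1_populations, "CEU")
  # sub-threshold ranks flag nothing
  ev3 <- toy_evidence(
    dind = data.frame(snp = "a", population = "YRI", rank = 0.94),
    fst = data.frame(snp = "a", pair = "YRI/CEU", rank = 0.94),
    gs = data.frame(population = "YRI", stat = "pi", rank = 0.06))
  expect_false(classify_targets(ev3, populations = pops3)$flagged)
  # R3: extreme single-variant rank, strictly greater than 0.999
  ev4 <- toy_evidence(dind = data.frame(snp = "a", population = "YRI",
                                        rank = 0.9995))
  cl4 <- classify_targets(ev4, populations = pops3)
  expect_true(cl4$flagged); expect_equal(cl4$rules, "R3")
  expect_false(classify_targets(
    toy_evidence(dind = data.frame(snp = "a", population = "YRI",
                                   rank = 0.999)),
    populations = pops3)$flagged)
  # family A + C in the same population
  ev5 <- toy_evidence(
    dind = data.frame(snp = "a", population = "CEU", rank = 0.96),
    gs = data.frame(population = "CEU", stat = "tajimas_d", rank = 0.04))
  expect_true(classify_targets(ev5, populations = pops3)$flagged)
  # same families in different populations do not combine
  ev6 <- toy_evidence(
    dind = data.frame(snp = "a", population = "CEU", rank = 0.96),
    gs = data.frame(population = "YRI", stat = "tajimas_d", rank = 0.04))
  expect_false(classify_targets(ev6, populations = pops3)$flagged)
})

test_that("classification is monotone in the ranks", {
  set.seed(12)
  for (k in 1:30) {
    ev <- toy_evidence(
      dind = data.frame(snp = sample(letters[1:4], 6, TRUE),
                        population = sample(pops3, 6, TRUE),
                        rank = runif(6)),
      fst = data.frame(snp = sample(letters[1:4], 4, TRUE),
                       pair = sample(c("YRI/CEU", "YRI/CHBJPT"), 4, TRUE),
                       rank = runif(4)),
      gs = data.frame(population = sample(pops3, 3),
                      stat = "pi", rank = runif(3)))
    before <- classify_targets(ev, populations = pops3)$flagged
    i <- sample.int(6, 1)
    ev$dind$rank[i] <- min(1, ev$dind$rank[i] + runif(1))
    after <- classify_targets(ev, populations = pops3)$flagged
    expect_true(after >= before)
  }
})

test_that("published evidence flags exactly the five candidate genes", {
  evs <- read_evidence(system.file("extdata", "brushborder_evidence.tsv",
                                   package = "sweepscan"))
  expect_length(evs, 8L)
  cls <- lapply(evs, classify_targets, populations = pops3)
  flagged <- names(evs)[vapply(cls, `[[`, TRUE, "flagged")]
  expect_setequal(flagged, c("SI", "TREH", "SLC5A1", "SLC2A2", "SLC2A5"))
  expect_true("R2" %in% cls$TREH$rules)     # all-populations DIND rule
  expect_equal(cls$TREH$supporting$r2, "rs527619")
})

test_that("resampling p matches exhaustive enumeration on a toy universe", {
  pos <- c(rep(TRUE, 3), rep(FALSE, 7))
  names(pos) <- paste0("g", 1:10)
  # exact: all 45 subsets of size 2
  exact <- resampling_pvalue(pos, observed_count = 1, set_size = 2,
                             exhaustive = TRUE)
  sets <- utils::combn(10, 2)
  brute <- mean(colSums(matrix(pos[sets], nrow = 2)) >= 1)
  expect_equal(exact$p, brute)
  expect_equal(length(exact$counts), 45L)
  # Monte-Carlo converges to the exact value
  mc <- resampling_pvalue(pos, 1, set_size = 2, n_samples = 4000, seed = 3)
  expect_lt(abs(mc$p - brute), 0.03)
  expect_identical(mc$p,
                   resampling_pvalue(pos, 1, 2, 4000, seed = 3)$p)
  expect_equal(resampling_pvalue(pos, 0, 2, 100, 1)$p, 1)
  expect_error(resampling_pvalue(pos, 1, set_size = 11), "set_size")
})

test_that("per-gene resampling criterion needs 3-pop DIND or 2 joint outliers", {
  ev_r2 <- toy_evidence(dind = data.frame(
    snp = "s", population = pops3, rank = 0.96))
  expect_true(resample_gene_positive(ev_r2, populations = pops3))
  ev_two <- toy_evidence(
    dind = data.frame(snp = c("a", "b"), population = "YRI",
                      rank = c(0.97, 0.98)),
    fst = data.frame(snp = c("a", "b"), pair = "YRI/CEU", rank = 0.99))
  expect_true(resample_gene_positive(ev_two, populations = pops3))
  # only one joint outlier variant: not positive
  ev_one <- toy_evidence(
    dind = data.frame(snp = c("a", "b"), population = "YRI",
                      rank = c(0.97, 0.10)),
    fst = data.frame(snp = c("a", "b"), pair = "YRI/CEU", rank = 0.99))
  expect_false(resample_gene_positive(ev_one, populations = pops3))
  # joint outliers in different populations do not combine
  ev_mix <- toy_evidence(
    dind = data.frame(snp = c("a", "b"), population = c("YRI", "CEU"),
                      rank = 0.97),
    fst = data.frame(snp = c("a", "b"),
                     pair = c("YRI/CHBJPT", "YRI/CEU"), rank = 0.99))
  expect_false(resample_gene_positive(ev_mix, populations = pops3))
})

test_that("scan_gene is deterministic and structurally complete", {
  cal <- fx_cal3()
  hm <- simulate_neutral(sim_params(40L, 40000L), default_demography(),
                         555L)
  r1 <- scan_gene(hm, cal, label = "g1")
  r2 <- scan_gene(hm, cal, label = "g1")
  expect_identical(r1$dind, r2$dind)
  expect_identical(r1$classification, r2$classification)
  expect_setequal(unique(r1$gene_stats$population), pops3)
  expect_true(all(r1$gene_stats$rank >= 0 & r1$gene_stats$rank <= 1))
  expect_true(all(r1$dind$rank >= 0 & r1$dind$rank <= 1, na.rm = TRUE))
  expect_setequal(unique(r1$fst$pair),
                  c("YRI/CEU", "YRI/CHBJPT", "CEU/CHBJPT"))
  expect_true(all(c("start", "end", "value", "below_threshold") %in%
                    names(r1$dh)))
})

test_that("scan_gene attaches simulation P values to outlier SNPs", {
  cal <- fx_cal3()
  cfg <- default_config(sim_n_iter = 15L)   # scaled for the test budget
  sw <- simulate_sweep(sim_params(40L, 40000L), default_demography(),
                       sweep_model(position = 20000L, target_daf = 0.8,
                                   population = "YRI"), 321L)
  res <- scan_gene(sw, cal, cfg, label = "sw",
                   sim_demography = default_demography(), sim_seed = 4L)
  expect_true("sim_p" %in% names(res$dind))
  out <- !is.na(res$dind$rank) & res$dind$rank >= cfg$rank_threshold
  if (any(out)) {
    expect_true(all(is.na(res$dind$sim_p[!out])))
    expect_true(all(res$dind$sim_p[out] >= 0 & res$dind$sim_p[out] <= 1,
                    na.rm = TRUE))
  }
})

test_that("candidate tables export and round-trip", {
  cal <- fx_cal3()
  res <- list()
  for (i in 1:3)
    res[[i]] <- scan_gene(simulate_neutral(sim_params(40L, 40000L),
                                           default_demography(), 900L + i),
                          cal, label = paste0("g", i))
  path <- tempfile(fileext = ".tsv")
  tab <- export_candidate_table(res, path = path)
  back <- read_candidate_table(path)
  n_flagged_snps <- sum(vapply(res, function(r) {
    if (!r$classification$flagged) return(0L)
    length(unique(c(
      r$dind$pos[!is.na(r$dind$rank) & r$dind$rank >= 0.95],
      r$fst$pos[!is.na(r$fst$rank) & r$fst$rank >= 0.95])))
  }, 0L))
  expect_equal(nrow(tab), n_flagged_snps)
  if (nrow(tab)) {
    expect_equal(back$pos, tab$pos)
    expect_equal(back$gene, tab$gene)
  } else {
    expect_equal(nrow(back), 0L)   # header-only file
  }
  # zero candidates always writes a readable header-only file
  path2 <- tempfile(fileext = ".tsv")
  empty <- list(list(classification = list(flagged = FALSE)))
  tab2 <- export_candidate_table(empty, path = path2)
  expect_equal(nrow(read_candidate_table(path2)), 0L)
})
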