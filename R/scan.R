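#' Define a gene scan region
#'
#' The scan covers the gene plus 50 kb of flank (25 kb up- and
#' down-stream by default), clipped at position 1.
#'
#' @param label gene label.
#' @param chrom chromosome.
#' @param gene_start,gene_end 1-based closed gene coordinates.
#' @param flank flank size on each side (bp).
#' @return a `gene_region` list with `gene_start`, `gene_end`,
#'   `scan_start`, `scan_end`.
#' @export
define_region <- function(label, chrom, gene_start, gene_end,
                          flank = 25000L) {
  if (gene_end < gene_start) stop("gene_end must be >= gene_start")
  structure(list(label = label, chrom = chrom,
                 gene_start = as.integer(gene_start),
                 gene_end = as.integer(gene_end),
                 scan_start = max(1L, as.integer(gene_start - flank)),
                 scan_end = as.integer(gene_end + flank)),
            class = "gene_region")
}

# vectorized per-SNP Weir-Cockerham FST over all sites for one pair;
# mirrors weir_cockerham_fst() (the scalar contract is the tested oracle)
.fst_pair_table <- function(haps, pop_a, pop_b) {
  pop_stats <- function(pop) {
    rows <- which(haps$sample_map$population == pop)
    m <- haps$alleles[rows, , drop = FALSE]
    sm <- haps$sample_map$sample[rows]
    first <- !duplicated(sm)
    m1 <- m[first, , drop = FALSE]; m2 <- m[!first, , drop = FALSE]
    ok <- !is.na(m1) & !is.na(m2)
    n <- colSums(ok)
    p <- colSums((m1 + m2) * ok, na.rm = TRUE) / (2 * n)
    het <- colSums((m1 != m2) & ok, na.rm = TRUE) / n
    list(n = n, p = p, het = het)
  }
  A <- pop_stats(pop_a); B <- pop_stats(pop_b)
  r <- 2
  nbar <- (A$n + B$n) / 2
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$het + B$n * B$het) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  fst <- ifelse(den == 0 | A$n < 1 | B$n < 1, NA_real_, a / den)
  pool_p <- (A$n * A$p + B$n * B$p) / (A$n + B$n)
  data.frame(site = seq_len(n_sites(haps)), pos = haps$positions,
             maf = pmin(pool_p, 1 - pool_p), fst = fst)
}

#' Build every calibration the scan needs from a control set
#'
#' Gene-level distributions of pi, Watterson's theta and Tajima's D per
#' population; MAF-binned per-SNP FST per population pair; DAF-binned
#' DIND per population (sentinels finalized over the pooled control
#' dataset); and the fifth-percentile DH window threshold per population.
#'
#' @param control a `control_set` from [generate_control_set()] (or any
#'   named list of [haplotype_matrix()] in `$genes`).
#' @param config a [default_config()] list.
#' @return a `scan_calibrations` list.
#' @export
build_calibrations <- function(control, config = default_config()) {
  genes <- control$genes
  pops <- populations(genes[[1]])
  gene_level <- list(); dind_cal <- list(); dh_thresh <- list()
  dind_max <- list()
  for (p in pops) {
    subs <- lapply(genes, subset_haps, population = p)
    gl <- list(
      pi = vapply(subs, nucleotide_diversity, 0),
      theta_w = vapply(subs, watterson_theta, 0),
      tajimas_d = vapply(subs, tajimas_d, 0))
    gene_level[[p]] <- lapply(gl, function(v)
      build_binned_calibration(NULL, v, "none"))
    dts <- lapply(subs, dind_table, flank_total = config$dind_flank_total,
                  max_missing = config$max_missing, finalize = FALSE)
    pool <- do.call(rbind, dts)
    pool <- pool[pool$computed, , drop = FALSE]
    if (nrow(pool) && any(!pool$sentinel))
      pool <- finalize_dind_sentinels(pool, config$sentinel_offset)
    dind_cal[[p]] <- build_binned_calibration(
      pool$daf, pool$dind, "DAF", n_bins = config$daf_bins,
      sentinel = pool$sentinel)
    dind_max[[p]] <- suppressWarnings(
      max(pool$dind[!pool$sentinel], na.rm = TRUE))
    dh <- unlist(lapply(subs, function(s)
      sliding_dh(s, window = config$window_bp, step = config$step_bp,
                 min_snps = config$min_snps_window)$value))
    dh_thresh[[p]] <- dh_window_threshold(dh[!is.na(dh)])
  }
  fst_cal <- list()
  if (length(pops) > 1L) {
    prs <- utils::combn(pops, 2)
    for (k in seq_len(ncol(prs))) {
      key <- paste(prs[1, k], prs[2, k], sep = "/")
      tab <- do.call(rbind, lapply(genes, .fst_pair_table,
                                   pop_a = prs[1, k], pop_b = prs[2, k]))
      tab <- tab[!is.na(tab$fst) & tab$maf > 0, , drop = FALSE]
      fst_cal[[key]] <- build_binned_calibration(
        tab$maf, tab$fst, "MAF", n_bins = config$maf_bins)
    }
  }
  structure(list(populations = pops, gene_level = gene_level,
                 dind = dind_cal, dind_max_finite = dind_max,
                 fst = fst_cal, dh_threshold = dh_thresh),
            class = "scan_calibrations")
}

#' Scan one gene region
#'
#' Computes gene-level statistics with their low-tail empirical ranks,
#' per-SNP FST and DIND with frequency-binned ranks, DH sliding windows
#' against the control fifth-percentile threshold, and the selection
#' classification — everything behind a candidate-table row.
#'
#' @param haps [haplotype_matrix()] covering the scan region (all
#'   populations).
#' @param calibrations a `scan_calibrations` from [build_calibrations()].
#' @param config a [default_config()] list.
#' @param label gene label.
#' @param gene_region optional `gene_region`; gene-level statistics are
#'   then restricted to the gene body (the SNP-level tables always use
#'   the full scan region).
#' @param sim_demography optional [demography_model()]: when supplied,
#'   coalescent-simulation P values ([dind_sim_pvalue()]) are added for
#'   every DIND outlier SNP (rank at or above the threshold), using
#'   `config$sim_n_iter` iterations on `config$sim_region_length` bp.
#' @param sim_seed seed for the simulation P values.
#' @return a `gene_scan_result` list with `gene_stats`, `dind`, `fst`,
#'   `dh`, and `classification`.
#' @export
scan_gene <- function(haps, calibrations, config = default_config(),
                      label = "gene", gene_region = NULL,
                      sim_demography = NULL, sim_seed = 1L) {
  pops <- calibrations$populations
  body_sites <- if (is.null(gene_region)) NULL else
    which(haps$positions >= gene_region$gene_start &
            haps$positions <= gene_region$gene_end)
  gene_stats <- do.call(rbind, lapply(pops, function(p) {
    sub <- subset_haps(haps, p)
    vals <- c(pi = nucleotide_diversity(sub, body_sites),
              theta_w = watterson_theta(sub, body_sites),
              tajimas_d = tajimas_d(sub, body_sites))
    data.frame(population = p, stat = names(vals), value = unname(vals),
               rank = vapply(names(vals), function(s)
                 rank_value(calibrations$gene_level[[p]][[s]], NULL,
                            vals[[s]]), 0),
               stringsAsFactors = FALSE)
  }))
  dind_tabs <- as.data.frame(data.table::rbindlist(lapply(pops, function(p) {
    dt <- dind_table(haps, p, config$dind_flank_total,
                     config$max_missing, finalize = FALSE)
    dt <- dt[dt$computed, , drop = FALSE]
    if (nrow(dt) == 0) return(NULL)
    dt$dind[dt$sentinel] <-
      calibrations$dind_max_finite[[p]] + config$sentinel_offset
    dt$rank <- rank_value(calibrations$dind[[p]], dt$daf, dt$dind,
                          dt$sentinel)
    testable <- dind_testable_bins(calibrations$dind[[p]])
    dt$rank[!testable[.bin_of(calibrations$dind[[p]], dt$daf)]] <- NA_real_
    dt$population <- p
    dt
  })))
  fst_tabs <- as.data.frame(data.table::rbindlist(
    lapply(names(calibrations$fst), function(key) {
      pr <- strsplit(key, "/")[[1]]
      tab <- .fst_pair_table(haps, pr[1], pr[2])
      tab <- tab[!is.na(tab$fst) & tab$maf > 0, , drop = FALSE]
      if (nrow(tab) == 0) return(NULL)
      tab$rank <- rank_value(calibrations$fst[[key]], tab$maf, tab$fst)
      tab$pair <- key
      tab
    })))
  dh_tabs <- do.call(rbind, lapply(pops, function(p) {
    w <- sliding_dh(subset_haps(haps, p), window = config$window_bp,
                    step = config$step_bp,
                    min_snps = config$min_snps_window)
    w$population <- p
    w$below_threshold <- w$defined &
      w$value <= calibrations$dh_threshold[[p]]
    w
  }))
  if (!is.null(sim_demography) && nrow(dind_tabs)) {
    dind_tabs$sim_p <- NA_real_
    out <- !is.na(dind_tabs$rank) & dind_tabs$rank >= config$rank_threshold
    for (i in which(out)) {
      sp <- dind_sim_pvalue(
        dind_tabs$dind[i], dind_tabs$daf[i], sim_demography,
        sim_params(n_haplotypes_per_pop =
                     sum(haps$sample_map$population ==
                           dind_tabs$population[i]),
                   region_length = config$sim_region_length),
        n_iter = config$sim_n_iter,
        seed = derive_seed(sim_seed, i),
        population = dind_tabs$population[i])
      dind_tabs$sim_p[i] <- sp$p
    }
  }
  evidence <- list(
    gene = label,
    gene_stats = gene_stats,
    dind = if (nrow(dind_tabs) == 0) NULL else
      data.frame(snp = dind_tabs$pos, population = dind_tabs$population,
                 rank = dind_tabs$rank, stringsAsFactors = FALSE),
    fst = if (nrow(fst_tabs) == 0) NULL else
      data.frame(snp = fst_tabs$pos, pair = fst_tabs$pair,
                 rank = fst_tabs$rank, stringsAsFactors = FALSE))
  cls <- classify_targets(evidence, populations = pops,
                          rank_threshold = config$rank_threshold,
                          extreme_rank = config$extreme_rank,
                          gene_stat_percentile = config$gene_stat_percentile)
  structure(list(label = label, gene_stats = gene_stats, dind = dind_tabs,
                 fst = fst_tabs, dh = dh_tabs, evidence = evidence,
                 classification = cls),
            class = "gene_scan_result")
}

#' Classify a gene as a selection target
#'
#' A gene is flagged when any of these holds:
#' \describe{
#'   \item{R1}{in one population, significant signals in at least two
#'     distinct feature families — A: a gene-level diversity/SFS statistic
#'     (pi, Watterson's theta or Tajima's D) at or below the control
#'     `gene_stat_percentile`; B: an FST rank at or above
#'     `rank_threshold` in a comparison involving the population; C: a
#'     DIND rank at or above `rank_threshold` in the population.}
#'   \item{R2}{one SNP with a significant DIND rank in every population.}
#'   \item{R3}{one SNP with a DIND rank strictly above `extreme_rank`.}
#' }
#' DH windows are confirmatory only and never enter the rules.
#'
#' @param evidence list with `gene`, `gene_stats` (population, stat,
#'   rank), `dind` (snp, population, rank) and `fst` (snp, pair, rank);
#'   `scan_gene()` builds this, or encode published evidence directly.
#' @param populations population labels R2 must cover (default: those in
#'   `evidence$gene_stats`, falling back to the DIND table).
#' @param rank_threshold,extreme_rank,gene_stat_percentile thresholds.
#' @return list with `flagged`, `rules` (subset of R1/R2/R3),
#'   `r1_populations`, `families` (per-population logical matrix) and
#'   `supporting` (SNPs behind R2/R3).
#' @export
classify_targets <- function(evidence, populations = NULL,
                             rank_threshold = 0.95, extreme_rank = 0.999,
                             gene_stat_percentile = 0.05) {
  if (is.null(populations)) {
    populations <- unique(c(evidence$gene_stats$population,
                            evidence$dind$population))
  }
  dd <- evidence$dind
  ff <- evidence$fst
  gs <- evidence$gene_stats
  fam <- sapply(populations, function(p) {
    c(A = !is.null(gs) && any(gs$population == p &
                                gs$stat %in% c("pi", "theta_w", "tajimas_d") &
                                !is.na(gs$rank) &
                                gs$rank <= gene_stat_percentile),
      B = !is.null(ff) && nrow(ff) > 0 &&
        any(grepl(paste0("(^|/)", p, "($|/)"), ff$pair) &
              !is.na(ff$rank) & ff$rank >= rank_threshold),
      C = !is.null(dd) && nrow(dd) > 0 &&
        any(dd$population == p & !is.na(dd$rank) &
              dd$rank >= rank_threshold))
  })
  fam <- matrix(fam, nrow = 3, dimnames = list(c("A", "B", "C"),
                                               populations))
  r1_pops <- populations[colSums(fam) >= 2]
  r1 <- length(r1_pops) > 0
  r2_snps <- character(0)
  # R2 is defined over a multi-population panel; with a single population
  # it would collapse onto "any significant SNP" and is therefore off
  if (length(populations) >= 2L && !is.null(dd) && nrow(dd)) {
    sig <- dd[!is.na(dd$rank) & dd$rank >= rank_threshold, , drop = FALSE]
    per_snp <- tapply(sig$population, sig$snp,
                      function(x) all(populations %in% x))
    r2_snps <- names(per_snp)[per_snp]
  }
  r2 <- length(r2_snps) > 0
  r3_snps <- if (!is.null(dd) && nrow(dd))
    unique(dd$snp[!is.na(dd$rank) & dd$rank > extreme_rank]) else character(0)
  r3 <- length(r3_snps) > 0
  rules <- c("R1", "R2", "R3")[c(r1, r2, r3)]
  list(flagged = r1 || r2 || r3, rules = rules, r1_populations = r1_pops,
       families = fam, supporting = list(r2 = r2_snps, r3 = r3_snps))
}

#' Per-gene positive call used by the resampling test
#'
#' A gene counts as positively selected in a resampled set when it
#' carries at least one variant with a significant DIND rank in every
#' population, or at least two variants that are outliers for both DIND
#' and FST in the same population.
#'
#' @inheritParams classify_targets
#' @return logical.
#' @export
resample_gene_positive <- function(evidence, populations = NULL,
                                   rank_threshold = 0.95) {
  if (is.null(populations))
    populations <- unique(c(evidence$gene_stats$population,
                            evidence$dind$population))
  dd <- evidence$dind; ff <- evidence$fst
  if (!is.null(dd) && nrow(dd)) {
    sig <- dd[!is.na(dd$rank) & dd$rank >= rank_threshold, , drop = FALSE]
    per_snp <- tapply(sig$population, sig$snp,
                      function(x) all(populations %in% x))
    if (length(populations) >= 2L && length(per_snp) && any(per_snp))
      return(TRUE)
    if (!is.null(ff) && nrow(ff)) {
      fsig <- ff[!is.na(ff$rank) & ff$rank >= rank_threshold, ,
                 drop = FALSE]
      for (p in populations) {
        dsnp <- unique(sig$snp[sig$population == p])
        fsnp <- unique(fsig$snp[grepl(paste0("(^|/)", p, "($|/)"),
                                      fsig$pair)])
        if (length(intersect(dsnp, fsnp)) >= 2L) return(TRUE)
      }
    }
  }
  FALSE
}

#' Gene-set resampling significance
#'
#' Draws `n_samples` sets of `set_size` control genes (without
#' replacement within a set), counts positives per set with the per-gene
#' criterion, and reports the fraction of sets with at least
#' `observed_count` positives. `exhaustive = TRUE` enumerates every
#' subset instead (exact P).
#'
#' @param gene_positive named logical vector: positive call per control
#'   gene (see [resample_gene_positive()]).
#' @param observed_count positives observed in the focal set.
#' @param set_size genes per draw (default 8).
#' @param n_samples number of draws (default 100).
#' @param seed integer seed.
#' @param exhaustive enumerate all subsets (requires a small universe).
#' @return list with `p`, `counts` and `n_samples`.
#' @export
resampling_pvalue <- function(gene_positive, observed_count, set_size = 8L,
                              n_samples = 100L, seed = 1L,
                              exhaustive = FALSE) {
  n <- length(gene_positive)
  if (set_size > n) stop("set_size exceeds the number of control genes")
  if (exhaustive) {
    if (choose(n, set_size) > 5e5)
      stop("universe too large for exhaustive enumeration")
    sets <- utils::combn(n, set_size)
    counts <- colSums(matrix(gene_positive[sets], nrow = set_size))
  } else {
    set.seed(seed)
    counts <- vapply(seq_len(n_samples), function(i)
      sum(gene_positive[sample.int(n, set_size)]), 0)
  }
  list(p = mean(counts >= observed_count), counts = counts,
       n_samples = length(counts))
}

#' Export a candidate-variant table
#'
#' One row per SNP supporting a flagged gene (any DIND or FST rank at or
#' above the outlier threshold), with the derived allele, per-population
#' DAF, per-population DIND rank, per-pair FST rank and annotation notes.
#' Writes TSV when `path` is given; [read_candidate_table()] round-trips
#' it losslessly.
#'
#' @param results list of `gene_scan_result` objects.
#' @param haps optional [haplotype_matrix()] used to add derived-allele
#'   nucleotides and per-population DAF.
#' @param path optional output TSV path.
#' @param rank_threshold outlier threshold for inclusion.
#' @param notes optional named character (names = SNP positions).
#' @return the candidate data.frame (invisibly when `path` is given).
#' @export
export_candidate_table <- function(results, haps = NULL, path = NULL,
                                   rank_threshold = 0.95, notes = NULL) {
  rows <- list()
  for (res in results) {
    if (!res$classification$flagged) next
    dd <- res$dind; ff <- res$fst
    snps <- sort(unique(c(
      if (!is.null(dd) && nrow(dd))
        dd$pos[!is.na(dd$rank) & dd$rank >= rank_threshold],
      if (!is.null(ff) && nrow(ff))
        ff$pos[!is.na(ff$rank) & ff$rank >= rank_threshold])))
    for (s in snps) {
      row <- list(gene = res$label, snp = as.character(s), pos = s)
      if (!is.null(dd)) for (p in unique(dd$population)) {
        hit <- dd[dd$pos == s & dd$population == p, , drop = FALSE]
        row[[paste0("daf_", p)]] <-
          if (nrow(hit)) hit$daf[1] else NA_real_
        row[[paste0("dind_rank_", p)]] <-
          if (nrow(hit)) hit$rank[1] else NA_real_
      }
      if (!is.null(ff)) for (k in unique(ff$pair)) {
        hit <- ff[ff$pos == s & ff$pair == k, , drop = FALSE]
        row[[paste0("fst_rank_", gsub("/", "_", k))]] <-
          if (nrow(hit)) hit$rank[1] else NA_real_
      }
      row$notes <- if (!is.null(notes) && as.character(s) %in% names(notes))
        notes[[as.character(s)]] else ""
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) data.table::rbindlist(rows, fill = TRUE) else
    data.table::data.table(gene = character(0), snp = character(0),
                           pos = integer(0), notes = character(0))
  out <- as.data.frame(out)
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t", na = "NA")
    return(invisible(out))
  }
  out
}

#' @rdname export_candidate_table
#' @export
read_candidate_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                  colClasses = list(character = "snp")))
}
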