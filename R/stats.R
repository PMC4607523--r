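# Mean number of pairwise differences between rows of a binary matrix.
# With complete data this is sum_j c_j (k - c_j) / choose(k, 2); pairs with
# missing calls are compared over mutually non-missing sites and rescaled
# by the fraction of sites compared (avoids downward bias).
.mean_pairwise <- function(m) {
  k <- nrow(m)
  if (k < 2L) stop("need >= 2 haplotypes")
  if (ncol(m) == 0L) return(0)
  if (!anyNA(m)) {
    cj <- colSums(m)
    return(sum(cj * (k - cj)) / (k * (k - 1) / 2))
  }
  tot <- 0; npair <- 0L; S <- ncol(m)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    nc <- sum(ok)
    if (nc == 0L) next
    tot <- tot + sum(m[i, ok] != m[j, ok]) * S / nc
    npair <- npair + 1L
  }
  if (npair == 0L) return(NA_real_)
  tot / npair
}

.hap_input <- function(haps, site_subset = NULL) {
  m <- if (inherits(haps, "haplotype_matrix")) haps$alleles else as.matrix(haps)
  if (!is.null(site_subset)) m <- m[, site_subset, drop = FALSE]
  m
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences between haplotypes, in units of
#' differences per region (divide by region length for per-bp values).
#'
#' @param haps a [haplotype_matrix()] or a 0/1 matrix (haplotypes x sites).
#' @param site_subset optional site (column) indices.
#' @return pi >= 0.
#' @export
nucleotide_diversity <- function(haps, site_subset = NULL) {
  .mean_pairwise(.hap_input(haps, site_subset))
}

#' Watterson's theta
#'
#' S / a_n with S the number of segregating sites and a_n = sum_(i<n) 1/i.
#'
#' @inheritParams nucleotide_diversity
#' @return theta_W >= 0.
#' @export
watterson_theta <- function(haps, site_subset = NULL) {
  m <- .hap_input(haps, site_subset)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 haplotypes")
  S <- .n_segregating(m)
  S / sum(1 / seq_len(n - 1L))
}

.n_segregating <- function(m) {
  cj <- colSums(m, na.rm = TRUE)
  nj <- nrow(m) - colSums(is.na(m))
  sum(cj > 0L & cj < nj)
}

#' Tajima's D
#'
#' Normalized difference between pi and Watterson's theta; negative under
#' an excess of rare alleles (as after a sweep or expansion).
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA` when there are no segregating sites (undefined).
#' @export
tajimas_d <- function(haps, site_subset = NULL) {
  m <- .hap_input(haps, site_subset)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 haplotypes")
  S <- .n_segregating(m)
  if (S == 0L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  num <- .mean_pairwise(m) - S / a1
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den == 0) {
    # n = 2: pi equals theta_W exactly and the variance degenerates
    if (abs(num) < 1e-12) return(0)
    return(NA_real_)
  }
  num / den
}

#' Normalized Fay and Wu's H (DH)
#'
#' DH = (pi - theta_L) / sqrt(Var), with theta_L = sum_i i xi_i / (n - 1)
#' the high-frequency-derived weighted estimator (xi_i = number of sites
#' with the derived allele in i copies) and the variance evaluated with
#' theta_W and theta^2 = S(S-1)/(a_n^2 + b_n). Strongly negative under an
#' excess of high-frequency derived alleles. Only polarized sites
#' contribute; unpolarized sites in the subset are dropped with a warning.
#'
#' @inheritParams nucleotide_diversity
#' @return DH, or `NA` when no polarized segregating sites (undefined).
#' @export
fay_wu_dh <- function(haps, site_subset = NULL) {
  if (inherits(haps, "haplotype_matrix")) {
    pol <- haps$polarized
    if (is.null(site_subset)) site_subset <- seq_len(n_sites(haps))
    drop <- !pol[site_subset]
    if (any(drop)) {
      warning(sum(drop), " unpolarized site(s) excluded from DH")
      site_subset <- site_subset[!drop]
    }
  }
  m <- .hap_input(haps, site_subset)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 haplotypes")
  cj <- colSums(m, na.rm = TRUE)
  nj <- n - colSums(is.na(m))
  seg <- cj > 0L & cj < nj
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  cj <- cj[seg]; nj <- nj[seg]
  pi <- sum(2 * cj * (nj - cj) / (nj * (nj - 1)))
  theta_l <- sum(cj / (nj - 1))
  an <- sum(1 / seq_len(n - 1L))
  bn <- sum(1 / seq_len(n - 1L)^2)
  bn1 <- bn + 1 / n^2
  theta_w <- S / an
  theta_sq <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * theta_sq
  (pi - theta_l) / sqrt(v)
}

#' DH in sliding windows
#'
#' 5 kb windows moving by 500 bp by default. Windows tile the region; the
#' last window is shortened at the region edge when the step does not
#' divide evenly. Windows with fewer than `min_snps` polarized segregating
#' sites are reported undefined.
#'
#' @param haps a [haplotype_matrix()].
#' @param region length-2 integer (1-based closed); default the matrix's.
#' @param window window length in bp.
#' @param step step in bp (0 < step <= window).
#' @param min_snps minimum polarized SNPs for a defined window.
#' @return data.frame with columns `start`, `end`, `n_snps`, `value`,
#'   `defined`.
#' @export
sliding_dh <- function(haps, region = NULL, window = 5000L, step = 500L,
                       min_snps = 3L) {
  if (step <= 0 || window < step) stop("need window >= step > 0")
  if (is.null(region)) region <- haps$region
  len <- region[2] - region[1] + 1L
  if (window >= len) {
    starts <- region[1]; ends <- region[2]
  } else {
    starts <- seq.int(region[1], region[2] - window + 1L, by = step)
    ends <- starts + window - 1L
    if (ends[length(ends)] < region[2]) {  # shortened edge window
      starts <- c(starts, starts[length(starts)] + step)
      ends <- c(ends, region[2])
    }
  }
  pol <- which(haps$polarized)
  res <- lapply(seq_along(starts), function(i) {
    idx <- pol[haps$positions[pol] >= starts[i] &
                 haps$positions[pol] <= ends[i]]
    seg <- idx[idx %in% polymorphic_sites(haps)]
    if (length(seg) < min_snps)
      return(data.frame(start = starts[i], end = ends[i],
                        n_snps = length(seg), value = NA_real_,
                        defined = FALSE))
    data.frame(start = starts[i], end = ends[i], n_snps = length(seg),
               value = fay_wu_dh(haps, seg), defined = TRUE)
  })
  do.call(rbind, res)
}

#' Per-SNP Weir-Cockerham FST for two populations
#'
#' Variance-components estimator with the full diploid decomposition:
#' among-population (a), among-individuals-within-population (b) and
#' within-individual (c) components computed from sample sizes, allele
#' frequencies and observed heterozygosities; returns a / (a + b + c).
#'
#' @param pop_a,pop_b lists with elements `n` (diploid individuals), `p`
#'   (allele frequency) and `het` (observed heterozygote frequency).
#' @return the FST estimate, or `NA` when a + b + c = 0 (monomorphic
#'   across both populations).
#' @export
weir_cockerham_fst <- function(pop_a, pop_b) {
  if (pop_a$n < 1 || pop_b$n < 1)
    stop("each population needs >= 1 genotyped diploid sample")
  ni <- c(pop_a$n, pop_b$n)
  pi_ <- c(pop_a$p, pop_b$p)
  hi <- c(pop_a$het, pop_b$het)
  r <- 2
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi_) / (r * nbar)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

#' FST at a site of a haplotype matrix
#'
#' Convenience wrapper deriving diploid counts, allele frequency and
#' observed heterozygosity per population from the phased matrix.
#'
#' @param haps a [haplotype_matrix()].
#' @param site site (column) index.
#' @param pop_a,pop_b population labels.
#' @return per-SNP FST estimate (see [weir_cockerham_fst()]).
#' @export
fst_site <- function(haps, site, pop_a, pop_b) {
  stats_of <- function(pop) {
    rows <- which(haps$sample_map$population == pop)
    g <- haps$alleles[rows, site]
    sm <- haps$sample_map$sample[rows]
    gt <- split(g, sm)
    gt <- gt[vapply(gt, function(x) !anyNA(x), TRUE)]
    if (!length(gt)) stop("no genotyped diploid sample in ", pop)
    list(n = length(gt),
         p = mean(unlist(gt)),
         het = mean(vapply(gt, function(x) x[1] != x[2], TRUE)))
  }
  weir_cockerham_fst(stats_of(pop_a), stats_of(pop_b))
}

#' Linkage disequilibrium r^2 between two sites
#'
#' @param col_i,col_j 0/1 haplotype allele vectors (same length).
#' @return r^2 in [0, 1], or `NA` if a site is monomorphic among the
#'   mutually non-missing haplotypes.
#' @export
ld_r2 <- function(col_i, col_j) {
  ok <- !is.na(col_i) & !is.na(col_j)
  x <- col_i[ok]; y <- col_j[ok]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(x == 1 & y == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# select the `flank_total` polymorphic flank sites nearest the focal site:
# balanced (flank_total/2 each side) when possible, borrowing from the
# longer side otherwise; NULL when fewer than flank_total exist
.select_flanks <- function(candidates, focal, flank_total) {
  lower <- rev(candidates[candidates < focal])
  upper <- candidates[candidates > focal]
  half <- flank_total %/% 2L
  n_lo <- min(length(lower), half)
  n_up <- min(length(upper), half)
  short <- flank_total - n_lo - n_up
  if (short > 0L) {
    extra_lo <- min(length(lower) - n_lo, short)
    n_lo <- n_lo + extra_lo
    n_up <- n_up + min(length(upper) - n_up, short - extra_lo)
  }
  if (n_lo + n_up < flank_total) return(NULL)
  sort(c(lower[seq_len(n_lo)], upper[seq_len(n_up)]))
}

#' DIND: derived intra-allelic nucleotide diversity test
#'
#' Partitions the haplotypes by their allele at the focal SNP and compares
#' mean pairwise diversity over a constant number of flanking variants
#' (default 40: 20 up- and 20 down-stream, borrowing from the longer side
#' near region edges): DIND = i_pi_A / i_pi_D. Large values indicate a
#' sweep on the derived allele. A monomorphic derived class (i_pi_D = 0)
#' is sentinel-flagged; [finalize_dind_sentinels()] later assigns those the
#' dataset maximum plus the sentinel offset.
#'
#' @param haps a [haplotype_matrix()] (typically one population, see
#'   [subset_haps()]).
#' @param focal_index site (column) index of the focal SNP (must be
#'   polarized).
#' @param flank_total number of flanking variants used (constant).
#' @param max_missing flank sites with a larger missing fraction are not
#'   used.
#' @return one-row data.frame: `site`, `pos`, `daf`, `i_pi_A`, `i_pi_D`,
#'   `dind`, `sentinel`, `computed`, `n_flank_used`.
#' @export
dind <- function(haps, focal_index, flank_total = 40L, max_missing = 0.1) {
  if (!haps$polarized[focal_index]) stop("focal site is not polarized")
  row0 <- data.frame(site = focal_index, pos = haps$positions[focal_index],
                     daf = NA_real_, i_pi_A = NA_real_, i_pi_D = NA_real_,
                     dind = NA_real_, sentinel = FALSE, computed = FALSE,
                     n_flank_used = 0L)
  g <- haps$alleles[, focal_index]
  keep <- !is.na(g)
  daf <- mean(g[keep])
  row0$daf <- daf
  cand <- setdiff(polymorphic_sites(haps, max_missing = max_missing),
                  focal_index)
  flanks <- .select_flanks(cand, focal_index, as.integer(flank_total))
  if (is.null(flanks)) return(row0)
  der <- which(keep & g == 1L); anc <- which(keep & g == 0L)
  if (length(der) < 2L || length(anc) < 2L) return(row0)
  ipa <- .mean_pairwise(haps$alleles[anc, flanks, drop = FALSE])
  ipd <- .mean_pairwise(haps$alleles[der, flanks, drop = FALSE])
  row0$i_pi_A <- ipa; row0$i_pi_D <- ipd
  row0$computed <- TRUE; row0$n_flank_used <- length(flanks)
  if (is.na(ipd) || is.na(ipa)) { row0$computed <- FALSE; return(row0) }
  if (ipd == 0) {
    row0$sentinel <- TRUE          # value assigned at dataset level
  } else {
    row0$dind <- ipa / ipd
  }
  row0
}

#' DIND for every polymorphic polarized site of one population
#'
#' @param haps a [haplotype_matrix()].
#' @param population population label (`NULL`: use all haplotypes).
#' @inheritParams dind
#' @param finalize apply [finalize_dind_sentinels()] to the table (skipped
#'   automatically if every computed value is a sentinel).
#' @return data.frame, one row per testable site (see [dind()]).
#' @export
dind_table <- function(haps, population = NULL, flank_total = 40L,
                       max_missing = 0.1, finalize = TRUE) {
  if (!is.null(population)) haps <- subset_haps(haps, population)
  sites <- polymorphic_sites(haps)
  sites <- sites[haps$polarized[sites]]
  rows <- lapply(sites, function(s) dind(haps, s, flank_total, max_missing))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), pos = integer(0), daf = numeric(0),
               i_pi_A = numeric(0), i_pi_D = numeric(0), dind = numeric(0),
               sentinel = logical(0), computed = logical(0),
               n_flank_used = integer(0))
  if (finalize && any(out$computed & !out$sentinel))
    out <- finalize_dind_sentinels(out)
  out
}

#' Assign sentinel DIND values (dataset maximum + offset)
#'
#' Sites whose derived class is monomorphic over the flanks (i_pi_D = 0)
#' cannot take a finite ratio; they receive the maximum finite DIND
#' obtained over the whole dataset plus a constant offset (default 20),
#' computed once per dataset pass.
#'
#' @param results data.frame from [dind()] / [dind_table()] rows.
#' @param offset sentinel offset added to the dataset maximum.
#' @return `results` with sentinel rows' `dind` filled in.
#' @export
finalize_dind_sentinels <- function(results, offset = 20) {
  sent <- results$sentinel & results$computed
  if (!any(sent)) return(results)
  finite <- results$dind[results$computed & !results$sentinel]
  finite <- finite[is.finite(finite)]
  if (!length(finite))
    stop("all DIND results are sentinels: no finite maximum to offset")
  results$dind[sent] <- max(finite) + offset
  results
}
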