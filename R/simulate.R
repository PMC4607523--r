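#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule used by every generator that needs several
#' independent streams. Stays below 2^31 so results are portable.
#'
#' @param seed master integer seed.
#' @param index stream index (>= 1).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483629)
}

#' Generate a synthetic control gene set
#'
#' Independent neutral regions standing in for the genome-wide control
#' genes against which every empirical rank is calibrated. Per-gene seeds
#' are derived deterministically from the master seed.
#'
#' @param n_genes number of control regions (>= 1).
#' @param params a [sim_params()] object (applies to every gene).
#' @param demography a [demography_model()].
#' @param seed master seed.
#' @return a `control_set`: list with `genes` (named list of
#'   [haplotype_matrix()]) and `seeds`.
#' @export
generate_control_set <- function(n_genes, params, demography, seed) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  seeds <- vapply(seq_len(n_genes), function(i) derive_seed(seed, i), 1L)
  genes <- lapply(seq_len(n_genes), function(i)
    simulate_neutral(params, demography, seeds[i]))
  names(genes) <- sprintf("ctrl%04d", seq_len(n_genes))
  structure(list(genes = genes, seeds = seeds), class = "control_set")
}

#' Generate outgroup alleles for polarization
#'
#' Each outgroup species carries the generator's true ancestral nucleotide
#' at every site, independently replaced with probability equal to its
#' divergence (substitutions per bp on the outgroup lineage) by a random
#' different nucleotide — emulating ancestral-state misassignment risk in
#' primate outgroup alignments.
#'
#' @param matrix a [haplotype_matrix()] whose sites carry `anc_allele`.
#' @param n_outgroups number of outgroup species (>= 1).
#' @param divergence per-outgroup substitutions per bp; scalar or vector of
#'   length `n_outgroups`; must be >= 0.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos`, `sample`, `allele1`.
#' @export
generate_outgroups <- function(matrix, n_outgroups, divergence, seed) {
  if (n_outgroups < 1) stop("n_outgroups must be >= 1")
  if (any(divergence < 0)) stop("divergence must be >= 0")
  divergence <- rep_len(divergence, n_outgroups)
  if (is.null(matrix$anc_allele))
    stop("haplotype matrix lacks ancestral nucleotide labels")
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  S <- n_sites(matrix)
  out <- lapply(seq_len(n_outgroups), function(g) {
    allele <- matrix$anc_allele
    flip <- stats::runif(S) < divergence[g]
    if (any(flip))
      allele[flip] <- vapply(allele[flip],
                             function(a) sample(setdiff(nts, a), 1L), "")
    data.frame(chrom = matrix$chrom, pos = matrix$positions,
               sample = sprintf("outgroup%d", g), allele1 = allele,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate low-coverage ancient genotype calls
#'
#' Emulates genotype tables of ancient/archaic individuals: each sample's
#' true diploid genotype at a site is drawn from the first population's
#' allele frequency under Hardy-Weinberg proportions; the per-site read
#' depth is Poisson(mean_coverage). Two alleles are reported when depth >=
#' `two_allele_depth`, a single (randomly drawn) allele when depth is in
#' [1, two_allele_depth), nothing when no reads cover the site.
#'
#' @param matrix a [haplotype_matrix()].
#' @param samples data.frame with columns `label`, `mean_coverage` (>= 0).
#' @param seed integer seed.
#' @param two_allele_depth minimum depth for a diploid genotype call.
#' @return data.frame with columns `chrom`, `pos`, `sample`, `allele1`,
#'   `allele2` (`allele2` is `NA` for single-allele calls, both `NA` for
#'   missing sites).
#' @export
generate_ancient <- function(matrix, samples, seed, two_allele_depth = 4L) {
  if (any(samples$mean_coverage < 0)) stop("mean_coverage must be >= 0")
  set.seed(seed)
  S <- n_sites(matrix)
  p <- allele_frequencies(matrix,
                          population = populations(matrix)[1])$freq
  anc <- matrix$anc_allele; der <- matrix$der_allele
  out <- lapply(seq_len(nrow(samples)), function(i) {
    g1 <- stats::rbinom(S, 1L, p); g2 <- stats::rbinom(S, 1L, p)
    depth <- stats::rpois(S, samples$mean_coverage[i])
    a1 <- ifelse(g1 == 1L, der, anc)
    a2 <- ifelse(g2 == 1L, der, anc)
    pick <- stats::runif(S) < 0.5
    one <- ifelse(pick, a1, a2)
    allele1 <- ifelse(depth >= two_allele_depth, a1,
                      ifelse(depth >= 1L, one, NA_character_))
    allele2 <- ifelse(depth >= two_allele_depth, a2, NA_character_)
    data.frame(chrom = matrix$chrom, pos = matrix$positions,
               sample = samples$label[i], allele1 = allele1,
               allele2 = allele2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
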