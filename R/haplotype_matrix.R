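#' Phased haplotype matrix
#'
#' The substrate of every statistic in the package: a binary matrix of phased
#' alleles (haplotypes in rows, segregating sites in columns) together with
#' physical positions, a haplotype-to-sample/population map and a per-site
#' polarization flag. Allele 0 is the ancestral state wherever the site is
#' polarized; at unpolarized sites 0/1 are an arbitrary but fixed labelling
#' of REF/ALT.
#'
#' @param alleles integer matrix, haplotypes x sites, values in \{0, 1, NA\}.
#' @param positions integer vector of 1-based physical positions, strictly
#'   increasing, one per column of `alleles`.
#' @param sample_map data.frame with columns `haplotype` (row index into
#'   `alleles`), `sample` and `population`. Every diploid sample must
#'   contribute exactly two haplotypes.
#' @param polarized logical per site; `TRUE` means the ancestral state is
#'   known and allele 0 is ancestral. Defaults to all `TRUE`.
#' @param chrom chromosome label.
#' @param region length-2 integer, 1-based closed interval covered by the
#'   data. Defaults to `range(positions)`.
#' @param anc_allele,der_allele optional per-site nucleotide labels for the
#'   ancestral/derived alleles (used when writing VCF or outgroup tables).
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, sample_map,
                             polarized = NULL, chrom = "chr1",
                             region = NULL, anc_allele = NULL,
                             der_allele = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (ncol(alleles) != length(positions))
    stop("number of columns of `alleles` must equal length(positions)")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("`positions` must be strictly increasing")
  if (any(!is.na(alleles) & alleles != 0L & alleles != 1L))
    stop("`alleles` must contain only 0, 1 or NA")
  sample_map <- as.data.frame(sample_map, stringsAsFactors = FALSE)
  need <- c("haplotype", "sample", "population")
  if (!all(need %in% names(sample_map)))
    stop("`sample_map` needs columns haplotype, sample, population")
  if (nrow(sample_map) != nrow(alleles))
    stop("`sample_map` must have one row per haplotype")
  per_sample <- table(sample_map$sample)
  if (any(per_sample != 2L))
    stop("every diploid sample must contribute exactly 2 haplotypes")
  if (is.null(polarized)) polarized <- rep(TRUE, length(positions))
  if (length(polarized) != length(positions))
    stop("`polarized` must have one flag per site")
  if (is.null(region)) {
    region <- if (length(positions)) range(positions) else c(1L, 1L)
  }
  structure(
    list(alleles = alleles, positions = positions,
         sample_map = sample_map, polarized = as.logical(polarized),
         chrom = chrom, region = as.integer(region),
         anc_allele = anc_allele, der_allele = der_allele),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  pops <- table(x$sample_map$population) / 2L
  cat("haplotype_matrix:", n_haplotypes(x), "haplotypes x",
      n_sites(x), "sites\n")
  cat("  region:", x$chrom,
      paste0("[", x$region[1], ", ", x$region[2], "]"), "\n")
  cat("  samples per population:",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  cat("  polarized sites:", sum(x$polarized), "/", n_sites(x), "\n")
  invisible(x)
}

#' @rdname haplotype_matrix
#' @param x a `haplotype_matrix`.
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' @rdname haplotype_matrix
#' @export
n_sites <- function(x) ncol(x$alleles)

#' @rdname haplotype_matrix
#' @export
populations <- function(x) unique(x$sample_map$population)

#' Subset a haplotype matrix
#'
#' Restrict to one population and/or a set of site indices. Sites that are
#' monomorphic after a population subset are kept (callers that need
#' polymorphic sites filter explicitly with [polymorphic_sites()]).
#'
#' @param x a `haplotype_matrix`.
#' @param population population label, or `NULL` to keep all haplotypes.
#' @param sites integer site (column) indices, or `NULL` to keep all.
#' @return a `haplotype_matrix`.
#' @export
subset_haps <- function(x, population = NULL, sites = NULL) {
  rows <- seq_len(n_haplotypes(x))
  if (!is.null(population)) {
    rows <- which(x$sample_map$population %in% population)
    if (!length(rows)) stop("no haplotypes in population ", population)
  }
  if (is.null(sites)) sites <- seq_len(n_sites(x))
  sm <- x$sample_map[rows, , drop = FALSE]
  sm$haplotype <- seq_along(rows)
  haplotype_matrix(
    x$alleles[rows, sites, drop = FALSE], x$positions[sites], sm,
    polarized = x$polarized[sites], chrom = x$chrom, region = x$region,
    anc_allele = x$anc_allele[sites], der_allele = x$der_allele[sites])
}

#' Indices of sites polymorphic within the matrix
#'
#' @param x a `haplotype_matrix`.
#' @param max_missing maximum tolerated fraction of missing haplotype calls
#'   at a site (sites above the cap are never reported polymorphic).
#' @return integer vector of column indices.
#' @export
polymorphic_sites <- function(x, max_missing = 1) {
  n_na <- colSums(is.na(x$alleles))
  cnt <- colSums(x$alleles, na.rm = TRUE)
  n_ok <- nrow(x$alleles) - n_na
  which(cnt > 0L & cnt < n_ok & n_na <= max_missing * nrow(x$alleles))
}

#' Per-site derived allele counts and frequencies
#'
#' Counts of allele 1 over non-missing haplotypes. When a site is polarized,
#' allele 1 is the derived allele and the frequency is a DAF; otherwise it
#' is simply the ALT frequency.
#'
#' @param x a `haplotype_matrix`.
#' @param population optional population restriction.
#' @return data.frame with columns `site`, `pos`, `count`, `n`, `freq`,
#'   `maf`, `polarized`.
#' @export
allele_frequencies <- function(x, population = NULL) {
  if (!is.null(population)) x <- subset_haps(x, population)
  cnt <- colSums(x$alleles, na.rm = TRUE)
  n <- nrow(x$alleles) - colSums(is.na(x$alleles))
  freq <- ifelse(n > 0, cnt / n, NA_real_)
  data.frame(site = seq_len(n_sites(x)), pos = x$positions,
             count = as.integer(cnt), n = as.integer(n), freq = freq,
             maf = pmin(freq, 1 - freq), polarized = x$polarized)
}
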