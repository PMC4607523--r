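#' Write a haplotype matrix as a minimal phased VCF
#'
#' REF is the allele-0 nucleotide, ALT the allele-1 nucleotide; polarized
#' sites carry the ancestral allele in the `AA` INFO tag; genotypes are
#' phased (`a|b`), one column per diploid sample.
#'
#' @param haps a [haplotype_matrix()].
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(haps, path) {
  samples <- unique(haps$sample_map$sample)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan",
           paste0("##contig=<ID=", haps$chrom, ">"),
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  nts <- haps$anc_allele %||% rep("A", n_sites(haps))
  der <- haps$der_allele %||% rep("T", n_sites(haps))
  rows <- vapply(seq_len(n_sites(haps)), function(j) {
    gts <- vapply(samples, function(s) {
      hh <- which(haps$sample_map$sample == s)
      a <- haps$alleles[hh, j]
      paste(ifelse(is.na(a), ".", a), collapse = "|")
    }, "")
    info <- if (haps$polarized[j]) paste0("AA=", nts[j]) else "."
    paste(c(haps$chrom, haps$positions[j],
            paste0("snp", haps$positions[j]), nts[j], der[j], ".",
            "PASS", info, "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Biallelic SNP records only; multi-allelic and non-SNP records are
#' skipped with a message. Unphased genotypes are an error unless
#' `allow_unphased = TRUE`, in which case they are randomly phased with
#' the run seed (documented override for statistics that only need
#' frequencies). The `AA` INFO tag, when present and matching REF or
#' ALT, polarizes the site (allele 0 recoded to ancestral).
#'
#' @param path VCF path (plain text).
#' @param sample_populations optional data.frame (`sample`, `population`);
#'   defaults to a single population `"pop1"` over all samples. Samples
#'   named here but absent from the VCF are an error.
#' @param region optional length-2 numeric: keep positions within.
#' @param allow_unphased randomly phase unphased genotypes.
#' @param seed seed for the random-phasing override.
#' @return a [haplotype_matrix()].
#' @export
read_vcf <- function(path, sample_populations = NULL, region = NULL,
                     allow_unphased = FALSE, seed = 1L) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("malformed VCF: no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- BiocGenerics::start(rr)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))[1]
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  is_snp <- lengths(alt_l) == 1L & nchar(ref) == 1L &
    nchar(vapply(as.list(alt_l), function(a) as.character(a)[1], "")) == 1L
  n_skip <- sum(!is_snp)
  if (n_skip) message(n_skip, " multi-allelic/non-SNP record(s) skipped")
  keep <- which(is_snp)
  if (!is.null(region))
    keep <- keep[pos[keep] >= region[1] & pos[keep] <= region[2]]
  samples <- colnames(gt)
  if (is.null(sample_populations))
    sample_populations <- data.frame(sample = samples,
                                     population = "pop1",
                                     stringsAsFactors = FALSE)
  missing <- setdiff(sample_populations$sample, samples)
  if (length(missing))
    stop("samples missing from VCF: ", paste(missing, collapse = ", "))
  samples <- sample_populations$sample
  gt <- gt[keep, samples, drop = FALSE]
  pos <- pos[keep]; ref <- ref[keep]
  alt <- vapply(as.list(alt_l[keep]),
                function(a) as.character(a)[1], "")
  aa <- VariantAnnotation::info(vcf)$AA
  aa <- if (is.null(aa)) rep(NA_character_, length(keep)) else
    as.character(aa)[keep]
  aa[aa %in% c(".", "")] <- NA_character_

  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    if (!allow_unphased)
      stop("unphased genotypes found (", sum(unphased), " record(s)); ",
           "set allow_unphased = TRUE to randomly phase them")
    set.seed(seed)
    swap <- matrix(stats::runif(length(gt)) < 0.5, nrow = nrow(gt))
    gt[unphased & swap] <- vapply(strsplit(gt[unphased & swap], "/"),
                                  function(x) paste(rev(x), collapse = "|"),
                                  "")
    gt <- gsub("/", "|", gt, fixed = TRUE)
  }
  split_gt <- strsplit(gt, "|", fixed = TRUE)
  bad <- lengths(split_gt) != 2L
  if (any(bad))
    stop("malformed VCF genotype at record line ",
         which(bad)[1], " (expect a|b)")
  h1 <- matrix(vapply(split_gt, `[[`, "", 1L), nrow = nrow(gt))
  h2 <- matrix(vapply(split_gt, `[[`, "", 2L), nrow = nrow(gt))
  to_int <- function(m) {
    m[m == "."] <- NA_character_
    matrix(as.integer(m), nrow = nrow(m))
  }
  # interleave: two haplotype rows per sample, sites in rows -> transpose
  n_s <- length(samples)
  alle <- matrix(NA_integer_, nrow = 2L * n_s, ncol = length(pos))
  alle[seq(1L, 2L * n_s, by = 2L), ] <- t(to_int(h1))
  alle[seq(2L, 2L * n_s, by = 2L), ] <- t(to_int(h2))
  polar <- !is.na(aa) & (aa == ref | aa == alt)
  flip <- polar & aa == alt
  if (any(flip)) {
    alle[, flip] <- 1L - alle[, flip]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
  }
  sm <- data.frame(haplotype = seq_len(2L * n_s),
                   sample = rep(samples, each = 2L),
                   population = rep(sample_populations$population, each = 2L),
                   stringsAsFactors = FALSE)
  ord <- order(pos)
  haplotype_matrix(alle[, ord, drop = FALSE], pos[ord], sm,
                   polarized = polar[ord], chrom = chrom,
                   anc_allele = ref[ord], der_allele = alt[ord])
}

#' Read gene regions from a BED file
#'
#' Standard 0-based half-open BED converted at the boundary to the
#' package's 1-based fully-closed coordinates, with scan flanks applied.
#'
#' @param path BED path.
#' @param flank flank size passed to [define_region()].
#' @return list of `gene_region` objects (empty for an empty file).
#' @export
read_regions <- function(path, flank = 25000L) {
  if (file.size(path) == 0) return(list())
  gr <- rtracklayer::import(path, format = "BED")
  labels <- gr$name
  if (is.null(labels) || anyNA(labels))
    labels <- paste0("region", seq_along(gr))
  if (anyDuplicated(labels))
    stop("duplicate region labels in BED: ",
         labels[duplicated(labels)][1])
  out <- lapply(seq_along(gr), function(i)
    define_region(labels[i], as.character(GenomeInfoDb::seqnames(gr))[i],
                  BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i],
                  flank = flank))
  stats::setNames(out, labels)
}

#' @rdname read_regions
#' @param regions list of `gene_region` objects.
#' @export
write_regions <- function(regions, path) {
  lines <- vapply(regions, function(r)
    paste(r$chrom, r$gene_start - 1L, r$gene_end, r$label, sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Tab-separated table helpers (deterministic column order)
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}
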