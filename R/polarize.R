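#' Infer the ancestral allele by outgroup parsimony
#'
#' The ancestral state is accepted only when at least `min_informative`
#' outgroup species carry an allele, they all agree, and the agreed allele
#' is one of the two human alleles. Anything else leaves the site
#' unpolarized (`NA`), including outgroup alleles absent from the human
#' sample (parsimony cannot place the human alleles in that case).
#'
#' @param human_alleles character vector of the two human alleles.
#' @param outgroup_alleles character vector of outgroup alleles; `NA`, `"N"`
#'   and `"-"` are uninformative.
#' @param min_informative minimum number of informative outgroups
#'   (default 4: e.g. human + chimpanzee + orangutan + macaque alignments).
#' @return the ancestral allele, or `NA_character_` (unpolarized).
#' @export
infer_ancestral <- function(human_alleles, outgroup_alleles,
                            min_informative = 4L) {
  if (!length(outgroup_alleles)) stop("supply >= 1 outgroup allele")
  inf <- outgroup_alleles[!is.na(outgroup_alleles) &
                            !outgroup_alleles %in% c("N", "-", "")]
  if (length(inf) < min_informative) return(NA_character_)
  u <- unique(inf)
  if (length(u) != 1L) return(NA_character_)
  if (!u %in% human_alleles) return(NA_character_)
  u
}

#' Polarize the sites of a haplotype matrix from an outgroup table
#'
#' Runs [infer_ancestral()] at every site; where the inferred ancestral
#' allele is the current allele-1 nucleotide the column coding is flipped
#' so that 0 is always ancestral at polarized sites. Sites with no
#' parsimony resolution get `polarized = FALSE`.
#'
#' @param haps a [haplotype_matrix()] with `anc_allele` / `der_allele`
#'   nucleotide labels (allele 0 / allele 1).
#' @param outgroups data.frame with columns `pos`, `sample`, `allele1`
#'   (as produced by [generate_outgroups()] or read from TSV).
#' @param min_informative passed to [infer_ancestral()].
#' @return the matrix with updated `polarized`, `anc_allele`, `der_allele`.
#' @export
polarize_sites <- function(haps, outgroups, min_informative = 4L) {
  by_pos <- split(outgroups$allele1, outgroups$pos)
  pol <- logical(n_sites(haps))
  for (j in seq_len(n_sites(haps))) {
    og <- by_pos[[as.character(haps$positions[j])]]
    if (is.null(og)) { pol[j] <- FALSE; next }
    a0 <- haps$anc_allele[j]; a1 <- haps$der_allele[j]
    anc <- infer_ancestral(c(a0, a1), og, min_informative)
    if (is.na(anc)) { pol[j] <- FALSE; next }
    pol[j] <- TRUE
    if (anc == a1) {          # flip coding so 0 = ancestral
      haps$alleles[, j] <- 1L - haps$alleles[, j]
      haps$anc_allele[j] <- a1
      haps$der_allele[j] <- a0
    }
  }
  haps$polarized <- pol
  haps
}

#' Ancient/archaic genotype state at a polarized site
#'
#' Maps the (up to two) observed alleles of a low-coverage ancient sample
#' onto \{ancestral, derived, het, single:ancestral, single:derived,
#' missing\}. Only one allele is reported when coverage did not allow
#' genotype inference; alleles matching neither the ancestral nor the
#' derived nucleotide are inconsistent and excluded (state
#' `"inconsistent"`, treated as uninformative downstream).
#'
#' @param anc,der ancestral and derived nucleotides of the site.
#' @param allele1,allele2 observed alleles (`NA` when absent).
#' @return a state string.
#' @export
ancient_state <- function(anc, der, allele1, allele2 = NA_character_) {
  valid <- function(a) !is.na(a) && a %in% c(anc, der)
  if (is.na(allele1) && is.na(allele2)) return("missing")
  if (!is.na(allele1) && !valid(allele1)) return("inconsistent")
  if (!is.na(allele2) && !valid(allele2)) return("inconsistent")
  if (!is.na(allele1) && !is.na(allele2)) {
    if (allele1 == anc && allele2 == anc) return("ancestral")
    if (allele1 == der && allele2 == der) return("derived")
    return("het")
  }
  one <- if (is.na(allele1)) allele2 else allele1
  if (one == anc) "single:ancestral" else "single:derived"
}

#' Annotate a variant with ancient-sample states
#'
#' @param variant list or one-row data.frame with `pos`, `anc`, `der`.
#' @param ancient_genotypes data.frame with columns `pos`, `sample`,
#'   `allele1`, `allele2` (see [generate_ancient()]).
#' @return named character vector of states, one per ancient sample
#'   covering the position (samples without a row are `"missing"`).
#' @export
annotate_ancient <- function(variant, ancient_genotypes) {
  rows <- ancient_genotypes[ancient_genotypes$pos == variant$pos, ,
                            drop = FALSE]
  out <- vapply(seq_len(nrow(rows)), function(i)
    ancient_state(variant$anc, variant$der,
                  rows$allele1[i], rows$allele2[i]), "")
  stats::setNames(out, rows$sample)
}

#' Classify a modern-human-specific site
#'
#' A site where every informative archaic sample displays the ancestral
#' allele (heterozygous or derived calls break the flag; single-allele
#' ancestral observations count as ancestral) while most modern humans
#' carry the derived allele (pooled DAF at or above `min_global_daf`).
#'
#' @param archaic_states character vector of states from
#'   [ancient_state()] for the archaic samples.
#' @param pooled_daf derived allele frequency pooled over modern
#'   populations.
#' @param min_global_daf threshold for "most modern humans" (default 0.5).
#' @return `TRUE`/`FALSE`, or `NA` when no archaic sample is informative.
#' @export
classify_modern_specific <- function(archaic_states, pooled_daf,
                                     min_global_daf = 0.5) {
  informative <- archaic_states[!archaic_states %in%
                                  c("missing", "inconsistent")]
  if (!length(informative)) return(NA)
  all(informative %in% c("ancestral", "single:ancestral")) &&
    pooled_daf >= min_global_daf
}

#' Per-variant summary table
#'
#' One row per site with derived/minor allele frequencies per population —
#' the record joined by every downstream annotation.
#'
#' @param haps a [haplotype_matrix()].
#' @return data.frame with columns `site`, `pos`, `anc`, `der`,
#'   `polarized`, then `daf_<pop>` and `maf_<pop>` per population and
#'   `daf_pooled`.
#' @export
variant_table <- function(haps) {
  out <- data.frame(site = seq_len(n_sites(haps)), pos = haps$positions,
                    anc = haps$anc_allele %||% NA_character_,
                    der = haps$der_allele %||% NA_character_,
                    polarized = haps$polarized,
                    stringsAsFactors = FALSE)
  for (p in populations(haps)) {
    af <- allele_frequencies(haps, p)
    out[[paste0("daf_", p)]] <- ifelse(haps$polarized, af$freq, NA_real_)
    out[[paste0("maf_", p)]] <- af$maf
  }
  af <- allele_frequencies(haps)
  out$daf_pooled <- ifelse(haps$polarized, af$freq, NA_real_)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
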