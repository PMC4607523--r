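#' Convert a long evidence table into per-gene classification evidence
#'
#' The long format has one row per piece of evidence with columns `gene`,
#' `type` (`dind`, `fst` or `gene_stat`), `snp`, `population`, `pair`,
#' `stat` and `rank`; the package ships the published brush-border gene
#' evidence in this format (`inst/extdata/brushborder_evidence.tsv`).
#'
#' @param df data.frame in the long evidence format.
#' @return named list of evidence lists, one per gene, each directly
#'   consumable by [classify_targets()] and [resample_gene_positive()].
#' @export
evidence_from_table <- function(df) {
  out <- lapply(split(df, df$gene), function(g) {
    list(
      gene = g$gene[1],
      gene_stats = {
        x <- g[g$type == "gene_stat", c("population", "stat", "rank")]
        if (nrow(x)) x else NULL
      },
      dind = {
        x <- g[g$type == "dind", c("snp", "population", "rank")]
        if (nrow(x)) x else NULL
      },
      fst = {
        x <- g[g$type == "fst", c("snp", "pair", "rank")]
        if (nrow(x)) x else NULL
      })
  })
  out[unique(df$gene)]
}

#' @rdname evidence_from_table
#' @param path TSV path (see [read_tsv()]); `#` comment lines allowed.
#' @export
read_evidence <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        na.strings = "NA"))
  evidence_from_table(df)
}
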