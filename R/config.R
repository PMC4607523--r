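#' Default pipeline configuration
#'
#' Every constant of the published scan procedure, overridable per run:
#' 40 DIND flanking variants, sentinel = dataset maximum + 20, 50 MAF
#' classes for FST, 100 DAF classes for DIND, 5,000/500 bp DH windows,
#' 25,000 bp gene flanks, outlier rank 0.95 and extreme single-variant
#' rank 0.999, DH fifth percentile, 2,000 coalescent iterations on
#' 20,000 bp regions, 100 resamples of 8 genes.
#'
#' @param ... name = value overrides of individual entries.
#' @return a named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    flank_bp            = 25000L,  # gene flank, each side
    window_bp           = 5000L,   # DH sliding window
    step_bp             = 500L,    # DH window step
    min_snps_window     = 3L,      # DH window defined
    dind_flank_total    = 40L,     # flanking variants per DIND
    sentinel_offset     = 20,      # i_pi_D = 0 -> dataset max + offset
    maf_bins            = 50L,     # FST calibration classes
    daf_bins            = 100L,    # DIND calibration classes
    rank_threshold      = 0.95,    # empirical outlier rank
    extreme_rank        = 0.999,   # single-variant DIND rule (strict >)
    gene_stat_percentile = 0.05,   # low tail for gene-level stats
    dh_percentile       = 0.05,    # DH confirmatory threshold
    sim_n_iter          = 2000L,   # coalescent iterations for DIND P
    sim_region_length   = 20000L,  # simulated region length (bp)
    resample_n          = 100L,    # gene-set resampling draws
    resample_set_size   = 8L,      # genes per draw
    min_global_daf      = 0.5,     # modern-human-specific threshold
    min_outgroups       = 4L,      # informative outgroups for parsimony
    max_missing         = 0.1)     # per-site missing cap in DIND flanks
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a flat key = value config file
#'
#' @param path file path.
#' @return for `read_config`, a `pipeline_config` (unknown keys rejected).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    if (is.numeric(v) && v == round(v) && abs(v) < 2^31) v <- as.integer(v)
    v
  })
  do.call(default_config, stats::setNames(vals, vapply(kv, `[[`, "", 1)))
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unname(unlist(config)), sep = " = "),
             path)
  invisible(path)
}
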