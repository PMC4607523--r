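#' Build a binned empirical calibration
#'
#' Bins control-set statistics by an allele-frequency variable (equal-width
#' bins: MAF over [0, 0.5] with 50 classes, DAF over [0, 1] with 100
#' classes by default) and retains the sorted values per bin — the
#' machinery behind every empirical percentile rank in the scan.
#' Sentinel-tagged values (DIND with a monomorphic derived class) are
#' counted per bin and always rank above the finite values.
#'
#' @param bin_value frequency per observation (MAF or DAF), ignored for
#'   `bin_variable = "none"`.
#' @param statistic numeric statistic per observation (finite, or the
#'   dataset-level sentinel value for sentinel-tagged observations).
#' @param bin_variable one of `"MAF"`, `"DAF"`, `"none"`.
#' @param n_bins number of equal-width classes (default 50 for MAF, 100
#'   for DAF, 1 for none).
#' @param sentinel optional logical vector tagging sentinel observations.
#' @return an `empirical_distribution` object.
#' @export
build_binned_calibration <- function(bin_value, statistic,
                                     bin_variable = c("none", "MAF", "DAF"),
                                     n_bins = NULL, sentinel = NULL) {
  bin_variable <- match.arg(bin_variable)
  if (is.null(n_bins))
    n_bins <- switch(bin_variable, MAF = 50L, DAF = 100L, none = 1L)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  keep <- !is.na(statistic)
  statistic <- statistic[keep]
  if (!length(statistic)) stop("empty input: no finite control values")
  if (is.null(sentinel)) sentinel <- rep(FALSE, length(statistic))
  else sentinel <- sentinel[keep]
  upper <- switch(bin_variable, MAF = 0.5, DAF = 1, none = 1)
  edges <- seq(0, upper, length.out = n_bins + 1L)
  idx <- if (bin_variable == "none") rep(1L, length(statistic)) else {
    bin_value <- bin_value[keep]
    pmin(pmax(findInterval(bin_value, edges, rightmost.closed = TRUE), 1L),
         n_bins)
  }
  values <- vector("list", n_bins)
  n_sent <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    in_b <- idx == b
    values[[b]] <- sort(statistic[in_b & !sentinel])
    n_sent[b] <- sum(in_b & sentinel)
  }
  n_tot <- lengths(values) + n_sent
  structure(list(bin_variable = bin_variable, n_bins = n_bins,
                 edges = edges, values = values, n_sentinel = n_sent,
                 n_total = n_tot, testable = n_tot > 0L),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat("empirical_distribution:", x$bin_variable, "x", x$n_bins,
      "bins,", sum(x$n_total), "control values",
      sprintf("(%d sentinels)\n", sum(x$n_sentinel)))
  invisible(x)
}

.bin_of <- function(dist, bin_value) {
  if (dist$bin_variable == "none") return(rep(1L, length(bin_value)))
  pmin(pmax(findInterval(bin_value, dist$edges, rightmost.closed = TRUE),
            1L), dist$n_bins)
}

#' Empirical percentile rank of a statistic
#'
#' Fraction of control values in the matching frequency bin at or below
#' the statistic, with midpoint correction for ties and the observation
#' included in its own reference set (the add-one convention of empirical
#' P values): rank = (n_less + (n_tied + 1) / 2) / (n + 1). This keeps
#' ranks off the exact 0/1 boundary, so a value merely topping a sparsely
#' populated bin cannot masquerade as an "extreme" (> 0.999) rank — at
#' small control sizes the saturated estimator otherwise fires the
#' extreme-rank rule spuriously. Sentinel observations tie with the bin's
#' sentinel mass above every finite value. Vectorized.
#'
#' @param dist an `empirical_distribution`.
#' @param bin_value frequency of the observation (recycled).
#' @param statistic observed statistic value(s).
#' @param sentinel logical: observation is a sentinel.
#' @return ranks in [0, 1]; `NA` where the bin is untestable (empty).
#' @export
rank_value <- function(dist, bin_value, statistic, sentinel = FALSE) {
  n <- max(length(statistic), length(bin_value))
  statistic <- rep_len(statistic, n)
  bin_value <- rep_len(if (is.null(bin_value)) 0 else bin_value, n)
  sentinel <- rep_len(sentinel, n)
  bins <- .bin_of(dist, bin_value)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- bins[i]
    if (!dist$testable[b]) next
    v <- dist$values[[b]]; ns <- dist$n_sentinel[b]
    ntot <- dist$n_total[b]
    if (sentinel[i]) {
      out[i] <- (length(v) + (ns + 1) / 2) / (ntot + 1)
    } else if (is.na(statistic[i])) {
      next
    } else {
      n_less <- sum(v < statistic[i])
      n_tied <- sum(v == statistic[i])
      out[i] <- (n_less + (n_tied + 1) / 2) / (ntot + 1)
    }
  }
  out
}

#' Testable DAF bins for the DIND test
#'
#' With low-coverage data most low-DAF bins have i_pi_D = 0 for the bulk
#' of control variants, so their 95th percentile is not a finite value and
#' the test is not applicable there. A bin is testable when fewer than 5%
#' of its control values are sentinels (and it is non-empty).
#'
#' @param dist a DIND `empirical_distribution` built with sentinel tags.
#' @return logical vector, one flag per bin.
#' @export
dind_testable_bins <- function(dist) {
  dist$n_total > 0L & dist$n_sentinel / pmax(dist$n_total, 1L) < 0.05
}

#' Fifth-percentile DH threshold from control windows
#'
#' @param control_window_values DH values of control-set sliding windows.
#' @param min_n minimum number of control windows required.
#' @return the empirical 5th percentile.
#' @export
dh_window_threshold <- function(control_window_values, min_n = 20L) {
  v <- control_window_values[!is.na(control_window_values)]
  if (length(v) < min_n)
    stop("need >= ", min_n, " control window values")
  unname(stats::quantile(v, 0.05, type = 7))
}

#' Simulation-based DIND P value
#'
#' Coalescent simulations under the demography (region length 20,000 bp
#' and 2,000 iterations by default) produce DIND-DAF value pairs through
#' the same [dind_table()] operation as the empirical pipeline; sentinels
#' are finalized over the pooled simulated dataset. The P value is the
#' plain proportion of simulated DIND values in the observed DAF's bin
#' that are at or above the observed DIND; a (k+1)/(n+1) corrected
#' version is also reported.
#'
#' @param observed_dind observed DIND value.
#' @param observed_daf observed derived allele frequency.
#' @param demography a [demography_model()] (typically the focal
#'   population's single-population model).
#' @param params a [sim_params()]; defaults follow the printed pipeline
#'   (20,000 bp regions).
#' @param n_iter number of coalescent iterations (printed default 2,000).
#' @param seed master seed (per-iteration seeds derived).
#' @param n_bins DAF classes (default 100).
#' @param flank_total DIND flank count (default 40).
#' @param population population of `demography` to score (default first).
#' @return list with `p` (plain proportion), `p_corrected`
#'   ((k+1)/(n+1)) and `n_in_bin`; `p` is `NA` with a warning when no
#'   simulated value falls in the observed bin.
#' @export
dind_sim_pvalue <- function(observed_dind, observed_daf, demography,
                            params = sim_params(), n_iter = 2000L, seed = 1L,
                            n_bins = 100L, flank_total = 40L,
                            population = NULL) {
  if (is.na(observed_daf)) stop("observed DAF must be defined")
  if (is.null(population)) population <- demography$populations[1]
  tabs <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    hm <- simulate_neutral(params, demography, derive_seed(seed, i))
    tabs[[i]] <- dind_table(hm, population, flank_total, finalize = FALSE)
  }
  pool <- do.call(rbind, tabs)
  pool <- pool[pool$computed, , drop = FALSE]
  if (any(!pool$sentinel)) pool <- finalize_dind_sentinels(pool)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin_obs <- pmin(pmax(findInterval(observed_daf, edges,
                                    rightmost.closed = TRUE), 1L), n_bins)
  bins <- pmin(pmax(findInterval(pool$daf, edges,
                                 rightmost.closed = TRUE), 1L), n_bins)
  v <- pool$dind[bins == bin_obs & !is.na(pool$dind)]
  if (!length(v)) {
    warning("no simulated DIND values in the observed DAF bin")
    return(list(p = NA_real_, p_corrected = NA_real_, n_in_bin = 0L))
  }
  k <- sum(v >= observed_dind)
  list(p = k / length(v), p_corrected = (k + 1) / (length(v) + 1),
       n_in_bin = length(v))
}
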