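# Shared heavy fixtures, built once per test run and cached. Sizes are
# scaled for the test budget: the control set uses 300 genes of 60 kb (a
# 10 kb gene body plus 25 kb flanks) in a constant-size population. The
# sample size (120 haplotypes = 60 diploids per population) matches the
# scale of the phased pilot panels the scan was designed for; smaller
# samples leave DAF bins with borderline monomorphic-derived (sentinel)
# rates that visibly inflate the DIND type-I error, and small control
# sets leave per-bin thresholds dominated by within-gene clustering of
# DIND values (see the methods vignette).

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fx_params <- function() sim_params(120L, 60000L)
fx_demog <- function() constant_demography(10000)

fx_control <- function() fx_cached("control",
  generate_control_set(300L, fx_params(), fx_demog(), seed = 42L))

fx_cal <- function() fx_cached("cal",
  build_calibrations(fx_control(), default_config()))

# neutral constant-size replicates of a 20 kb region (n = 120). 1000
# replicates rather than the minimum 300: the Monte-Carlo SE of the mean
# (~0.05 at 300) would otherwise dominate the +/-0.15 calibration band,
# whose true values are about -0.09 (Tajima's D) and +0.08 (DH) here.
fx_neutral_reps <- function() fx_cached("neutral_reps", {
  p <- sim_params(120L, 20000L)
  d <- fx_demog()
  td <- dh <- numeric(1000)
  for (i in seq_len(1000)) {
    hm <- simulate_neutral(p, d, 100000L + i)
    td[i] <- tajimas_d(hm)
    dh[i] <- fay_wu_dh(hm)
  }
  list(tajimas_d = td, dh = dh)
})

# small 3-population control set + calibrations for multi-pop scan tests
fx_control3 <- function() fx_cached("control3",
  generate_control_set(30L, sim_params(40L, 40000L), default_demography(),
                       seed = 77L))

fx_cal3 <- function() fx_cached("cal3",
  build_calibrations(fx_control3(), default_config()))
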