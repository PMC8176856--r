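# The default-seed study cohort (50 cases) and its sweep are expensive to
# build, so they are generated once per test run and memoized.

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$cohort))
    .cohort_cache$cohort <- generate_cohort(cohort_config(seed = 1))
  .cohort_cache$cohort
}

default_sweep <- function() {
  if (is.null(.cohort_cache$sweep)) {
    coh <- default_cohort()
    .cohort_cache$sweep <- sweep_cohort(coh$cases, coh$ground_truth)
  }
  .cohort_cache$sweep
}

# A noise-free, blur-free acquisition model with unit soft-tissue background:
# the painted image is then exactly binary inside the VOI.
ideal_model <- function(peak_bg = 1.0) {
  background_model(
    soft_tissue = list(median = peak_bg, range = c(peak_bg, peak_bg)),
    noise_sd = 0, psf_fwhm_mm = 0)
}
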