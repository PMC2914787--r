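# Shared, lazily computed simulation products reused by several acceptance
# checks (computing them once keeps the suite's runtime dominated by a
# single desk-scale sweep rather than three).
.sweep_cache <- new.env(parent = emptyenv())

# Desk-scale reference sweep: shifting landscape, uniform kernel,
# mu = 0.05..1.0 step 0.05, 300 founders, 300 generations, 3 replicates.
shared_desk_sweep <- function() {
  if (is.null(.sweep_cache$desk)) {
    .sweep_cache$desk <- sweep_mu(
      seq(0.05, 1.0, by = 0.05), reps = 3,
      landscape_cfg = landscape_config("shifting"),
      repro_cfg = reproduction_config(kernel = "uniform"),
      generations = 300L, n_init = 300L, base_seed = 20260101)
  }
  .sweep_cache$desk
}

# Coarse normal-kernel sweep used only to locate the population transition.
shared_normal_sweep <- function() {
  if (is.null(.sweep_cache$normal)) {
    .sweep_cache$normal <- sweep_mu(
      seq(0.1, 1.5, by = 0.2), reps = 2,
      landscape_cfg = landscape_config("shifting"),
      repro_cfg = reproduction_config(kernel = "normal"),
      generations = 150L, n_init = 300L, base_seed = 20260102,
      measure_diversity = FALSE)
  }
  .sweep_cache$normal
}

# Smallest mu at which the across-replicate mean population exceeds the
# threshold (the sharp population rise).
transition_mu <- function(sweep, threshold = 1000) {
  o <- sweep[order(sweep$mu), ]
  hit <- which(o$mean_population > threshold)
  if (!length(hit)) Inf else o$mu[hit[1]]
}
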