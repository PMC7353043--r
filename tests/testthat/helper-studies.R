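# Cached full-scale study runs shared between acceptance-level tests, so
# each expensive simulation happens once per test session.

.study_cache <- new.env(parent = emptyenv())

study_get <- function(name, fun) {
  if (!exists(name, envir = .study_cache)) assign(name, fun(), envir = .study_cache)
  get(name, envir = .study_cache)
}

# study conditions: 4 replicate fields of 250 cells, capable fraction 0.482,
# PKA-responsive fraction 0.912, nested default hormone panel; 250 radius-15
# cells need a 1024 px field
study_config <- function(seed = 1L) {
  spark_config(n_cells = 250, frac_capable = 0.482,
               frac_pka_responsive = 0.912,
               frame_shape = c(1024L, 1024L), seed = seed)
}

study_forskolin <- function() {
  study_get("forskolin", function()
    run_population_study(study_config(), protocol_forskolin(),
                         field_seeds = 1:4))
}

study_bnz <- function() {
  study_get("bnz", function()
    run_population_study(study_config(), protocol_direct_pka(),
                         field_seeds = 1:4))
}

study_hormone <- function(h) {
  study_get(paste0("hormone_", h), function()
    run_population_study(study_config(), protocol_hormone(h),
                         field_seeds = 1:4))
}

study_sequential <- function() {
  study_get("sequential", function() {
    prot <- protocol_sequential(c("adenosine", "noradrenaline"))
    lapply(1:4, function(s) {
      cfg <- study_config(s)
      calls <- run_field(cfg, prot)$calls
      list(ov = sequential_overlap(calls),
           n_gated = length(unique(calls$cell)))
    })
  })
}

study_clones <- function() {
  study_get("clones", function() run_clone_study(seed = 1L))
}
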