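# Memoised default pipeline runs shared across test blocks (several checks
# interrogate the same seeded study simulations).
.pipeline_cache <- new.env(parent = emptyenv())

cached_run <- function(seed, direction = "sem_to_spat") {
  key <- paste(direction, seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_pipeline(
      pipeline_config(seed = seed, direction = direction),
      dvc_references = FALSE)
  }
  .pipeline_cache[[key]]
}

series_at <- function(ms, duration) {
  ms$series$mean[ms$series$duration_ms == duration]
}
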