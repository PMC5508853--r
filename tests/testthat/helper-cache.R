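## One demo pipeline run is shared by the pipeline and acceptance tests;
## computing it lazily here keeps each test file self-contained without
## repeating the ~1 minute simulation.
.run_cache <- new.env(parent = emptyenv())

cached_demo_run <- function(seed = 1, pld = 30) {
  key <- sprintf("s%d_pld%g", seed, pld)
  if (is.null(.run_cache[[key]])) {
    cfg <- demo_config(seed = seed, pld = pld)
    .run_cache[[key]] <- run_pipeline(cfg)
  }
  .run_cache[[key]]
}
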