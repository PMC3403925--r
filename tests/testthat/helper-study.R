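# Scaled-down study bundles, computed once per test session and shared
# across test files (the full design is 28 arrays; a small genome keeps the
# suite fast without changing the statistical structure).

study_bundle_cached <- local({
  b <- NULL
  function() {
    if (is.null(b)) {
      cfg <- study_config(
        genome = list(chromosome_lengths = c(chr1 = 3e5, chr2 = 3e5),
                      spacing = c(1000, 2000)),
        analysis = list(cbs_permutations = 150))
      b <<- run_study(cfg, seed = 42)
    }
    b
  }
})

null_bundle_cached <- local({
  b <- NULL
  function() {
    if (is.null(b)) {
      cfg <- study_config(
        genome = list(chromosome_lengths = c(chr1 = 1e5, chr2 = 1e5),
                      spacing = c(1000, 2000)),
        analysis = list(cbs_permutations = 100),
        preset = "null")
      b <<- run_study(cfg, seed = 7)
    }
    b
  }
})
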