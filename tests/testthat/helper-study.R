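# The full-design validation study is expensive, so it is computed once per
# test session and shared by the tests that assess study-level behaviour.
.study_cache <- new.env(parent = emptyenv())

default_study_result <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- run_validation_study(sim_config(seed = 20260922L))
  }
  .study_cache$res
}
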