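# One end-to-end training of the desk-scale preset, shared (memoized)
# across test files so the expensive fit runs at most once per session.

.trained_env <- new.env(parent = emptyenv())

get_tiny_run <- function() {
  if (!is.null(.trained_env$run)) return(.trained_env$run)
  preset <- tiny_preset(seed = 1L)
  cases <- phantom_corpus(preset$n_cases, preset$phantom, seed = 11L)
  ck <- pretrain(cases, preset$train_config, preset$net_config, preset$loss)
  .trained_env$run <- list(preset = preset, cases = cases, ck = ck,
                           test = cases[ck$split$test],
                           val = cases[ck$split$val])
  .trained_env$run
}
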