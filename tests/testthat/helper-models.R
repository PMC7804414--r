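# Desk-scale models are trained once per test session and shared across
# test files (training dominates the suite's runtime).
get_desk_models <- function() {
  if (is.null(.fixture_env$desk))
    .fixture_env$desk <- desk_models(seed = 1)
  .fixture_env$desk
}
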