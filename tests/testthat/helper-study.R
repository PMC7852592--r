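# The replicated reference study is expensive; build it once and share it
# across the acceptance checks.

referenceStudy <- function() {
  memoFixture("referenceStudy", function() {
    runReferenceStudy(seed = 20200714L, replicates = 10L)
  })
}
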