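## long-running FE checks: report every failure instead of aborting early
options(testthat.progress.max_fails = 100L)
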