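# The acceptance checks report every deviation from the reference values
# individually; make sure a handful of quantitative misses never aborts
# the remainder of the suite.
options(testthat.progress.max_fails = 1e6)
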