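# cache shared across acceptance blocks (the stepwise toy result is costly)
.acceptance_cache <- new.env(parent = emptyenv())
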