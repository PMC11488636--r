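# Mutable cache shared across acceptance blocks (the 20-min calibrated
# model is expensive; the closed-loop block reuses it when available).
efp_acceptance_cache <- new.env(parent = emptyenv())
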