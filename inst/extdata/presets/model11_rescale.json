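{"label": "zero inputs rescaled by +0.5", "spatial": "both", "zero_mode": "rescale_half"}
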