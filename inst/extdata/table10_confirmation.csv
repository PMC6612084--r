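combination,defective,good,total
A1B3C2D2,35,235,270
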