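parameter,value
NoiseTresInt,0
ionization,+
default_tol_ppm,10
network_mode,exact
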