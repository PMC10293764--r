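element,max_count
C,14
O,3
N,2
H,23
[13C],1
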