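element,max_count
C,15
O,1
N,2
H,13
[13C],1
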