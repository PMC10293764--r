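element,max_count
C,10
S,1
O,3
N,3
H,12
[13C],1
[34S],1
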