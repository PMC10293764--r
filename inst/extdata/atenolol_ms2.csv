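mz,intensity
56.0491,1
72.0804,1
74.0597,1
98.0973,1
116.1079,1
133.0651,1
145.0648,1
162.0914,1
164.0705,1
173.0597,1
178.0867,1
180.1022,1
190.0866,1
191.0898,1
208.0976,1
225.1239,1
267.1709,1
268.1747,1
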