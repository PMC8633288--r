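>CARG0001.syn carg_box_synthetic
A  [   0   0  50  50  50  50  50  50   0   0 ]
C  [ 100 100   0   0   0   0   0   0   0   0 ]
G  [   0   0   0   0   0   0   0   0 100 100 ]
T  [   0   0  50  50  50  50  50  50   0   0 ]
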