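>DBOX_SYN synthetic DBP-like Dbox stand-in
A  [ 1  1 16  1  1  2 17 16]
C  [ 2  1  2  1  1  1  1  2]
G  [ 1  2  1  1 16  1  1  1]
T  [16 16  1 17  2 16  1  1]
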