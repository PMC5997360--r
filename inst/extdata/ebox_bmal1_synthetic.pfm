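>EBOX_SYN synthetic BMAL1-like Ebox stand-in
A  [16  1  1 17  1  0  1  0  2  1]
C  [ 2  1 17  1 18  1  1  2  1 15]
G  [ 1 17  1  1  0 18  1 17  2  1]
T  [ 1  1  1  1  1  1 17  1 15  3]
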