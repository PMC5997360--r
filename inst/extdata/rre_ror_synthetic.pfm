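>RRE_SYN synthetic ROR-like RRE stand-in
A  [15 16  2  1  2 15  1  1  1  2 16]
C  [ 2  1  2  1  1  2  1  1  1 16  2]
G  [ 2  2  2 16  1  2 17 17  1  1  1]
T  [ 1  1 14  2 16  1  1  1 17  1  1]
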