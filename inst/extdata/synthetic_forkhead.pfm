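>SYNFKH1 synthetic_forkhead_like
A [ 12 68  2 95  1 94 90  5 20 ]
C [ 30  4  3  1  2  1  2  8 25 ]
G [ 28  6  4  2  1  2  3  4 30 ]
T [ 30 22 91  2 96  3  5 83 25 ]
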