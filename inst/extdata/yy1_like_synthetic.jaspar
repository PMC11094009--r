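>YY1_like_synthetic
A [  2  8  1  1 60  2 55 50  4  3 ]
C [ 55  2 58 60  1  2  1  3  2  4 ]
G [  2 48  1  1  1 58  2  3  2 50 ]
T [  3  4  2  0  0  0  4  6 54  5 ]
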