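>TATA_synthetic TATA-box consensus (synthetic counts, not a measured matrix)
A [ 10  95   5  90  60  85  55  60 ]
C [  5   0   3   2   2   3   5   5 ]
G [  5   2   2   3   3   7   5  30 ]
T [ 80   3  90   5  35   5  35   5 ]
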