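%%MatrixMarket matrix coordinate integer general
3 4 10
1 1 6
2 1 4
3 1 10
1 2 50
3 2 50
1 3 6
2 3 4
3 3 10
1 4 10
3 4 10
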