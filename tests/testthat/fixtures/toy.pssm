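
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M  -6  -5  -4  -3  -2  -1   0   1   2   3   4   5   6  -6  -5  -4  -3  -2  -1   0  0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.30 0.00
    2 K  -5  -4  -3  -2  -1   0   1   2   3   4   5   6  -6  -5  -4  -3  -2  -1   0   1  0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.30 0.00
    3 C  -4  -3  -2  -1   0   1   2   3   4   5   6  -6  -5  -4  -3  -2  -1   0   1   2  0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.30 0.00
    4 W  -3  -2  -1   0   1   2   3   4   5   6  -6  -5  -4  -3  -2  -1   0   1   2   3  0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.30 0.00
    5 A  -2  -1   0   1   2   3   4   5   6  -6  -5  -4  -3  -2  -1   0   1   2   3   4  0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.30 0.00

                      K         Lambda
Standard Ungapped    0.1337     0.3114
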