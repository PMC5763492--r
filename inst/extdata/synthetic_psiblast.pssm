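
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
              A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V    A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    5  -3   3   4  -4   0   1   0   1   2   0  -2   6   2  -3  -4   3   2   1  -2   10  17  11   1   2   9  15  10   1   8   7   6   7   6  19  12  16   4  17   4  0.60 0.63
    2 L    6  -4   1  -3   2  -4  -4   6   1   0   7   1   0   1  -4   6  -1   6  -2  -2   18  10   6   2  10  20  11  16   0  16   7  17  19  10   2   4   6  12  16   7  0.17 0.95
    3 K    4  -3   4   6  -3   5   3  -2   2   2  -1   4  -1   3   2   3   1   5   4  -2   15  16   3  11  17   3  10   8   4  15  17   7   8  20   9  17   2   3   2  16  0.88 0.86
    4 A    8   6  -2   4   1   5  -3  -1   5   0   1   6   3   0   3   1  -1   1   3   5   11  10   0  11  12   8  11  15  19   9  15  11  15   5  18   8  18   0   7  11  0.52 1.40
    5 V   -4  -2  -1  -2   0   4  -4   3   2  -2   6  -3  -4   6  -3   5   6  -3  -1   8    4  13  16  10   7   0   0   3   3   4   5   6  19  17  20  14   7   8  20   2  0.08 0.89
    6 R    3   7  -3   4   6   3   6  -3   3   1  -3   3  -2   4   0  -2  -2   3  -2   4    2  18  20  11   3  14  13  11   5  19  11   9   1   8   1  20   3   1   9  15  0.31 1.23
    7 D    5   0   0   8   1   3   5   2   6   1   1   1   4  -3  -1   6   1   1  -1   4    8   4  17   6  16   4  14  17  10   0   5   3   0   8   5   0   4  18  14   2  0.60 0.68
    8 T    2   6   4   1  -1   5   0   2  -3   6  -1   1   6   6  -3   3   5   1   6   4    7   3  15   7  18  19   1   6  18   1  16  20  11   4  12   7  17  19   2  15  0.79 1.22
    9 K    3   2   2  -4   2   2   0   5   5   5   3   7  -1  -3  -4  -2   5   0   2  -3    3   7  17   5   3   1  15   0   8   8  14   6  16  11   1   6   2  12   7  18  0.91 1.16
   10 S   -1   2  -3   1  -2   6  -3   1  -3   3   6   0  -4   3   1   7   5  -3   3  -2    6  10  18  13  10   9  10   1   3  15  13   7  17   4  20   9  16   1  12  19  0.18 1.12
   11 K    1   2   0   1   2  -3   2  -2  -3   2  -3   8  -4  -4   4  -2   5  -4  -4   5    7  19   4  12   2  20  14   4   1   7   3  10  13  20   1   8   2  19  18   4  0.48 0.68
   12 E    5  -1  -2  -4  -4   6   8  -3   1   0   4  -2   6  -1  -1  -2   5   3  -4  -3    8   5   2  12   4  12   3  20   5  20  20   5   9   5   2  12  10  19   4   5  0.59 0.92
   13 G   -3   3  -4   4  -3   0   4   4   0  -2  -4  -3  -2   1  -1   6   3   0   2  -2    4  17  13  18   9  14   9   6   5   8  20   7  16   0   6   6  16  15   7   9  1.00 1.38
   14 F   -1   6   2   5  -1  -2  -4   6   6   3  -2  -4  -1   5   5  -4   6   5  -4  -2   14  19  16  14  14  13  10  20   5  17   3  14  16   3   8  13  17  19   0  17  0.85 1.02
   15 P    6  -2   2   6  -4   4  -2   2   4   4   1   6   3  -2   7  -1   1  -1   0  -3    2  19  15  17  12  20   9   8  16  17   5   8  18  10   0   9  16   1   3  10  0.64 0.93
   16 L   -2   2   0   4   3   2  -4  -4  -1  -3   4   4   1   1   4  -2   4   4   5  -2   12  13   8   2   4  19  10  17   7   4  18  15  15  17  20   4   9  11  19  18  0.60 1.31
   17 I    3   5   2  -4   5   6   6  -3   6   7  -3   6   2   4   2   0  -4   4   2   3   16  10  15  10  15  20   5  18  15  12   8  20  19   7  15  18  18   5   4   4  0.68 0.75
   18 W   -1  -1   4   3   4   2   5  -4   4  -2   0  -3   4   0  -2  -4   5   6   4  -4    0  16   5  13   4  19   6   4  10  18  15   4  12  12  19  19  16  20  18   7  0.98 0.89
   19 T   -1   5  -1   0  -2   6   4   2   6   1   4  -2   5  -1  -2   2   5   4   4  -2    6   4  11  11  19  12  20  20  20  15  19  11  17  11   9   5  10   3  12  12  0.59 1.14
   20 N    6   4   7   2   5  -4  -3  -4  -4  -4  -2  -3  -2   4  -4   4  -1   0   5   1   11   0   5  17  20  11  15  10  12   9  16   1  15   5  19  14   8  11   1   6  0.82 1.24
   21 Y    2  -3   6   2  -4   6  -2   6  -2   4   3   2  -4   1  -2  -2   5   0   7  -1    4   8  13  16   3  17  17  19  20   3   6   2   5   6  12  17  15  19  13  10  0.64 0.77

                      K         Lambda
Standard Ungapped    0.1335     0.3113
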