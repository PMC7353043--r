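%%MatrixMarket matrix coordinate integer general
10 20 30
3 3 1
1 6 1
2 6 2
5 6 1
6 6 1
1 7 1
3 7 1
5 7 1
7 7 1
5 8 1
6 9 1
1 11 1
1 12 1
5 12 1
9 12 1
4 13 2
5 13 2
1 14 3
4 14 2
8 14 1
2 15 3
6 15 2
7 15 1
1 16 1
4 18 1
5 18 1
10 18 1
1 19 2
4 19 1
8 19 2
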