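4 0
4 1
4 2
4 3
5 3
5 4
5 2
5 1
6 1
6 0
6 2
6 3
7 6
7 5
7 3
7 1
8 2
8 1
8 4
8 7
9 2
9 8
9 5
9 4
10 5
10 1
10 7
10 3
11 6
11 4
11 3
11 5
12 4
12 11
12 2
12 8
13 11
13 7
13 1
13 8
14 12
14 5
14 3
14 13
15 8
15 13
15 3
15 5
16 10
16 0
16 1
16 6
17 12
17 8
17 4
17 7
18 6
18 4
18 1
18 7
19 3
19 18
19 11
19 14
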