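moca,mmse
0,0
1,2
2,4
3,6
4,8
5,9
6,11
7,12
8,14
9,15
10,16
11,17
12,18
13,19
14,20
15,21
16,22
17,22
18,23
19,24
20,24
21,25
22,26
23,26
24,27
25,28
26,28
27,29
28,29
29,30
30,30
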