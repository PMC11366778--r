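rudas,mmse
0,0
1,2
2,4
3,5
4,6
5,7
6,8
7,9
8,10
9,11
10,12
11,13
12,14
13,15
14,17
15,18
16,19
17,20
18,21
19,22
20,23
21,24
22,25
23,26
24,26
25,27
26,28
27,28
28,29
29,29
30,30
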