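value
1
7
7
2
4
5
5
2
1
5
5
3
3
4
6
5
7
6
4
3
6
1
4
6
4
2
2
2
2
5
2
5
3
6
6
4
7
1
4
5
2
5
6
3
3
5
5
6
6
3
5
7
0
2
7
7
6
6
3
3
5
4
1
1
3
5
5
5
4
6
1
2
6
4
6
4
5
3
6
3
2
4
2
3
3
4
5
3
3
1
3
4
1
7
6
2
6
6
3
3
3
5
2
3
4
5
4
3
3
3
4
3
2
3
4
1
1
4
5
6
4
5
0
7
7
4
3
2
6
4
4
5
1
7
1
4
3
3
5
5
5
1
3
3
5
4
2
6
4
3
6
4
4
1
2
5
6
6
3
6
3
3
5
4
4
3
2
5
5
5
5
3
2
5
2
5
6
5
7
0
3
3
2
1
7
6
6
6
4
3
4
5
6
6
6
7
7
6
5
0
2
6
2
3
1
2
6
0
5
7
6
5
3
1
7
7
5
5
6
6
6
5
6
7
5
4
2
2
0
3
3
5
0
5
4
1
4
3
4
3
4
7
6
5
7
7
5
5
1
5
2
5
4
4
3
5
4
4
6
1
2
2
4
5
6
4
4
1
2
2
4
2
5
6
6
7
2
7
4
3
7
4
2
2
5
5
2
1
4
4
4
5
6
7
7
4
6
0
2
4
4
5
4
5
4
0
1
1
0
3
5
1
3
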