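1	30
2	5
3	9
4	21
5	20
6	17
7	4
8	8
9	27
10	1
11	19
12	13
13	22
14	18
15	6
16	23
17	25
18	29
19	2
20	16
21	12
22	7
23	10
24	28
25	11
26	15
27	24
28	3
29	14
30	26
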