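10	10
10	10
19	10
19	10
28	10
28	10
7	28
7	28
2	10
2	7
15	10
15	28
22	10
22	15
8	2
8	7
3	2
3	28
23	10
23	7
25	28
25	2
21	10
21	28
12	10
12	21
29	3
29	28
26	10
26	3
20	2
20	3
6	19
6	21
14	21
14	10
11	2
11	10
5	2
5	14
4	22
4	20
13	21
13	21
16	2
16	6
27	20
27	10
17	19
17	10
30	20
30	10
9	2
9	2
24	21
24	13
18	12
18	2
1	10
1	3
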