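scenario	N1	N	beta	phi	p
1	15	500	0.1-0.2	0.94-0.99	0.1-0.3
2	15	500	0.1-0.2	0.94-0.99	0.4-0.6
3	15	500	0.1-0.2	0.94-0.99	0.7-0.9
4	30	500	0.1-0.2	0.94-0.99	0.1-0.3
5	30	500	0.1-0.2	0.94-0.99	0.4-0.6
6	30	500	0.1-0.2	0.94-0.99	0.7-0.9
7	15	2000	0.1-0.2	0.94-0.99	0.1-0.3
8	15	2000	0.1-0.2	0.94-0.99	0.4-0.6
9	15	2000	0.1-0.2	0.94-0.99	0.7-0.9
10	30	2000	0.1-0.2	0.94-0.99	0.1-0.3
11	30	2000	0.1-0.2	0.94-0.99	0.4-0.6
12	30	2000	0.1-0.2	0.94-0.99	0.7-0.9
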