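chrom	length_mb	gc_percent	detected	expected
1	59.58	36.4	171	137.6
2	59.64	36.7	158	137.7
3	62.63	36.9	162	144.6
4	78.09	38.4	342	180.3
5	72.5	36.4	174	167.4
6	60.27	36.4	139	139.2
7	74.28	36.7	160	171.5
8	54.3	36.5	113	125.4
9	56.46	36.5	131	130.4
10	45.42	36.6	101	104.9
11	45.48	36.4	105	105
12	49.18	36.3	110	113.6
13	52.19	36.5	110	120.5
14	52.66	36.6	131	121.6
15	48.04	36.8	111	110.9
16	55.27	36.5	127	127.6
17	53.46	36.6	104	123.5
18	51.02	36.6	117	117.8
19	48.45	36.4	118	111.9
20	55.2	36.6	123	127.5
21	45.93	36.6	112	106.1
22	39.13	37	105	90.4
23	46.22	36.7	97	106.7
24	42.17	36.3	83	97.4
25	37.5	36.6	92	86.6
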