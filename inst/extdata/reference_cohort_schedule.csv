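patient_id,response,total_bed_gy,bed_per_fraction_gy
1,RS,72,14.4
2,NR,59.5,11.9
3,NR,72,14.4
4,NR,100,20
5,NR,59.5,11.9
6,RS,54.8,11.0
7,RS,72,14.4
8,NR,72,14.4
9,NR,72,14.4
10,RS,59.5,11.9
11,NR,100,20.0
12,NR,100,20.0
13,RS,100,20.0
14,RS,132,26.4
15,RS,100,20.0
16,RS,100,20.0
17,NR,100,20.0
18,RS,61.5,12.3
19,RS,100,20.0
20,RS,100,20.0
21,NR,100,20.0
22,NR,100,20.0
23,NR,100,20.0
24,NR,100,20.0
25,NR,100,20.0
26,NR,100,20.0
27,NR,100,20.0
28,NR,100,20.0
29,NR,100,20.0
30,NR,72,14.4
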