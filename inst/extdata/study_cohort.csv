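patient_id,stage,lowest_cmc,highest_cmc,metastasis,event_day
1,3B,0,2,No,317
2,3B,0,2,No,152
3,Unknown,0,0,No,2889
4,3B,0,1,No,2974
5,1A,0,1,No,1186
6,3,0,1,No,2480
7,3A,0,1,No,358
8,1A,0,1,No,1876
9,2C,0,1,No,102
10,2B,0,2,No,1583
11,3B,0,2,No,251
12,3,2,61,Yes,192
13,3B,0,16,Yes,212
14,3B,3,209,Yes,1852
15,3C,3,54,Yes,730
16,2C,0,19,Yes,951
17,3,0,7,Yes,786
18,Mucosal,0,34,Yes,266
19,1B,11,301,Yes,723
20,3B,43,234,Yes,547
21,2A,1,3,Yes,1670
22,3A,1,74,Yes,405
23,3A,7,83,Yes,624
24,3,1,3,Yes,2240
25,3C,34,240,Yes,220
26,Mucosal,33,100,Yes,934
27,Mucosal,3,161,Yes,1506
28,3B,0,5,Yes,378
29,3C,2,63,No,383
30,3B,11,129,No,213
31,3B,0,4,No,468
32,3C,4,100,No,2490
33,3C,0,56,No,1233
34,3A,0,50,No,435
35,3B,1,423,No,513
36,3A,0,11,No,495
37,3A,0,13,No,205
38,3B,2,4,No,468
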