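"epoch_index","onset_s","stage"
1,0,"W"
2,30,"W"
3,60,"N1"
4,90,"N1"
5,120,"N2"
6,150,"N2"
7,180,"N2"
8,210,"N2"
9,240,"N2"
10,270,"N2"
11,300,"N2"
12,330,"N2"
13,360,"N2"
14,390,"N2"
15,420,"N2"
16,450,"N2"
17,480,"N2"
18,510,"N2"
19,540,"N2"
20,570,"N2"
21,600,"N2"
22,630,"N2"
23,660,"N2"
24,690,"N2"
25,720,"N3"
26,750,"N3"
27,780,"N3"
28,810,"N3"
29,840,"N3"
30,870,"N3"
31,900,"N3"
32,930,"N3"
33,960,"N3"
34,990,"N3"
35,1020,"N3"
36,1050,"N3"
37,1080,"N3"
38,1110,"N3"
39,1140,"N3"
40,1170,"N3"
41,1200,"N3"
42,1230,"N3"
43,1260,"N3"
44,1290,"N3"
45,1320,"N3"
46,1350,"N3"
47,1380,"N3"
48,1410,"N3"
49,1440,"N3"
50,1470,"N3"
51,1500,"N3"
52,1530,"N3"
53,1560,"N3"
54,1590,"N3"
55,1620,"N2"
56,1650,"N2"
57,1680,"N2"
58,1710,"N2"
59,1740,"N2"
60,1770,"N2"
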