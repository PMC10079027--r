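"label_id","name","volume_mm3"
1,"Brain-Stem",21500
2,"Left-Cerebellum-White-Matter",14500
3,"Right-Cerebellum-White-Matter",14790
4,"Left-VentralDC",4100
5,"Right-VentralDC",4182
6,"Left-Cerebral-White-Matter",225000
7,"Right-Cerebral-White-Matter",229500
8,"Left-Lateral-Ventricle",8300
9,"Right-Lateral-Ventricle",8466
10,"Left-Inf-Lat-Vent",400
11,"Right-Inf-Lat-Vent",408
12,"Left-choroid-plexus",750
13,"Right-choroid-plexus",765
14,"Left-vessel",60
15,"Right-vessel",61.2
16,"3rd-Ventricle",1100
17,"4th-Ventricle",1700
18,"CSF",1000
19,"Optic-Chiasm",210
20,"WM-hypointensities",1600
21,"Left-Thalamus-Proper",7500
22,"Right-Thalamus-Proper",7650
23,"Left-Caudate",3700
24,"Right-Caudate",3774
25,"Left-Putamen",5100
26,"Right-Putamen",5202
27,"Left-Pallidum",1800
28,"Right-Pallidum",1836
29,"Left-Hippocampus",4200
30,"Right-Hippocampus",4284
31,"Left-Amygdala",1700
32,"Right-Amygdala",1734
33,"Left-Accumbens-area",600
34,"Right-Accumbens-area",612
35,"Left-Cerebellum-Cortex",52000
36,"Right-Cerebellum-Cortex",53040
37,"ctx-lh-bankssts",2600
38,"ctx-lh-caudalanteriorcingulate",1900
39,"ctx-lh-caudalmiddlefrontal",6300
40,"ctx-lh-cuneus",3100
41,"ctx-lh-entorhinal",1800
42,"ctx-lh-fusiform",9500
43,"ctx-lh-inferiorparietal",12800
44,"ctx-lh-inferiortemporal",10100
45,"ctx-lh-isthmuscingulate",2500
46,"ctx-lh-lateraloccipital",11300
47,"ctx-lh-lateralorbitofrontal",7300
48,"ctx-lh-lingual",6500
49,"ctx-lh-medialorbitofrontal",5300
50,"ctx-lh-middletemporal",10000
51,"ctx-lh-parahippocampal",2100
52,"ctx-lh-paracentral",3600
53,"ctx-lh-parsopercularis",4600
54,"ctx-lh-parsorbitalis",2100
55,"ctx-lh-parstriangularis",3900
56,"ctx-lh-pericalcarine",2200
57,"ctx-lh-postcentral",9900
58,"ctx-lh-posteriorcingulate",3100
59,"ctx-lh-precentral",13500
60,"ctx-lh-precuneus",9800
61,"ctx-lh-rostralanteriorcingulate",2400
62,"ctx-lh-rostralmiddlefrontal",15800
63,"ctx-lh-superiorfrontal",22800
64,"ctx-lh-superiorparietal",12500
65,"ctx-lh-superiortemporal",11400
66,"ctx-lh-supramarginal",10000
67,"ctx-lh-frontalpole",900
68,"ctx-lh-temporalpole",2300
69,"ctx-lh-transversetemporal",1100
70,"ctx-lh-insula",6700
71,"ctx-rh-bankssts",2678
72,"ctx-rh-caudalanteriorcingulate",1957
73,"ctx-rh-caudalmiddlefrontal",6489
74,"ctx-rh-cuneus",3193
75,"ctx-rh-entorhinal",1854
76,"ctx-rh-fusiform",9785
77,"ctx-rh-inferiorparietal",13184
78,"ctx-rh-inferiortemporal",10403
79,"ctx-rh-isthmuscingulate",2575
80,"ctx-rh-lateraloccipital",11639
81,"ctx-rh-lateralorbitofrontal",7519
82,"ctx-rh-lingual",6695
83,"ctx-rh-medialorbitofrontal",5459
84,"ctx-rh-middletemporal",10300
85,"ctx-rh-parahippocampal",2163
86,"ctx-rh-paracentral",3708
87,"ctx-rh-parsopercularis",4738
88,"ctx-rh-parsorbitalis",2163
89,"ctx-rh-parstriangularis",4017
90,"ctx-rh-pericalcarine",2266
91,"ctx-rh-postcentral",10197
92,"ctx-rh-posteriorcingulate",3193
93,"ctx-rh-precentral",13905
94,"ctx-rh-precuneus",10094
95,"ctx-rh-rostralanteriorcingulate",2472
96,"ctx-rh-rostralmiddlefrontal",16274
97,"ctx-rh-superiorfrontal",23484
98,"ctx-rh-superiorparietal",12875
99,"ctx-rh-superiortemporal",11742
100,"ctx-rh-supramarginal",10300
101,"ctx-rh-frontalpole",927
102,"ctx-rh-temporalpole",2369
103,"ctx-rh-transversetemporal",1133
104,"ctx-rh-insula",6901
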