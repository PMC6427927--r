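region_index,region_name,macro_region,hemisphere,x,y
1,Precentral_L,Frontal,L,-20,83
2,Precentral_R,Frontal,R,20,83
3,Frontal_Sup_L,Frontal,L,-22.9,84
4,Frontal_Sup_R,Frontal,R,22.9,84
5,Frontal_Sup_Orb_L,Frontal,L,-25.7,85
6,Frontal_Sup_Orb_R,Frontal,R,25.7,85
7,Frontal_Mid_L,Frontal,L,-28.6,86
8,Frontal_Mid_R,Frontal,R,28.6,86
9,Frontal_Mid_Orb_L,Frontal,L,-31.4,87
10,Frontal_Mid_Orb_R,Frontal,R,31.4,87
11,Frontal_Inf_Oper_L,Frontal,L,-34.3,88
12,Frontal_Inf_Oper_R,Frontal,R,34.3,88
13,Frontal_Inf_Tri_L,Frontal,L,-37.1,89
14,Frontal_Inf_Tri_R,Frontal,R,37.1,89
15,Frontal_Inf_Orb_L,Frontal,L,-40,90
16,Frontal_Inf_Orb_R,Frontal,R,40,90
17,Rolandic_Oper_L,Frontal,L,-42.9,91
18,Rolandic_Oper_R,Frontal,R,42.9,91
19,Supp_Motor_Area_L,Frontal,L,-45.7,92
20,Supp_Motor_Area_R,Frontal,R,45.7,92
21,Olfactory_L,Frontal,L,-48.6,93
22,Olfactory_R,Frontal,R,48.6,93
23,Frontal_Sup_Medial_L,Frontal,L,-51.4,94
24,Frontal_Sup_Medial_R,Frontal,R,51.4,94
25,Frontal_Med_Orb_L,Frontal,L,-54.3,95
26,Frontal_Med_Orb_R,Frontal,R,54.3,95
27,Rectus_L,Frontal,L,-57.1,96
28,Rectus_R,Frontal,R,57.1,96
29,Insula_L,Insular,L,-20,48
30,Insula_R,Insular,R,20,48
31,Cingulum_Ant_L,Limbic,L,-20,38
32,Cingulum_Ant_R,Limbic,R,20,38
33,Cingulum_Mid_L,Limbic,L,-28,40.8
34,Cingulum_Mid_R,Limbic,R,28,40.8
35,Cingulum_Post_L,Limbic,L,-36,43.6
36,Cingulum_Post_R,Limbic,R,36,43.6
37,Hippocampus_L,Limbic,L,-44,46.4
38,Hippocampus_R,Limbic,R,44,46.4
39,ParaHippocampal_L,Limbic,L,-52,49.2
40,ParaHippocampal_R,Limbic,R,52,49.2
41,Amygdala_L,Limbic,L,-60,52
42,Amygdala_R,Limbic,R,60,52
43,Calcarine_L,Occipital,L,-20,-67
44,Calcarine_R,Occipital,R,20,-67
45,Cuneus_L,Occipital,L,-28,-64.2
46,Cuneus_R,Occipital,R,28,-64.2
47,Lingual_L,Occipital,L,-36,-61.4
48,Lingual_R,Occipital,R,36,-61.4
49,Occipital_Sup_L,Occipital,L,-44,-58.6
50,Occipital_Sup_R,Occipital,R,44,-58.6
51,Occipital_Mid_L,Occipital,L,-52,-55.8
52,Occipital_Mid_R,Occipital,R,52,-55.8
53,Occipital_Inf_L,Occipital,L,-60,-53
54,Occipital_Inf_R,Occipital,R,60,-53
55,Fusiform_L,Temporal,L,-20,3
56,Fusiform_R,Temporal,R,20,3
57,Postcentral_L,Parietal,L,-20,-27
58,Postcentral_R,Parietal,R,20,-27
59,Parietal_Sup_L,Parietal,L,-28,-24.2
60,Parietal_Sup_R,Parietal,R,28,-24.2
61,Parietal_Inf_L,Parietal,L,-36,-21.4
62,Parietal_Inf_R,Parietal,R,36,-21.4
63,SupraMarginal_L,Parietal,L,-44,-18.6
64,SupraMarginal_R,Parietal,R,44,-18.6
65,Angular_L,Parietal,L,-52,-15.8
66,Angular_R,Parietal,R,52,-15.8
67,Precuneus_L,Parietal,L,-60,-13
68,Precuneus_R,Parietal,R,60,-13
69,Paracentral_Lobule_L,Frontal,L,-60,97
70,Paracentral_Lobule_R,Frontal,R,60,97
71,Caudate_L,SCGM,L,-20,28
72,Caudate_R,SCGM,R,20,28
73,Putamen_L,SCGM,L,-33.3,32.7
74,Putamen_R,SCGM,R,33.3,32.7
75,Pallidum_L,SCGM,L,-46.7,37.3
76,Pallidum_R,SCGM,R,46.7,37.3
77,Thalamus_L,SCGM,L,-60,42
78,Thalamus_R,SCGM,R,60,42
79,Heschl_L,Temporal,L,-26.7,5.3
80,Heschl_R,Temporal,R,26.7,5.3
81,Temporal_Sup_L,Temporal,L,-33.3,7.7
82,Temporal_Sup_R,Temporal,R,33.3,7.7
83,Temporal_Pole_Sup_L,Temporal,L,-40,10
84,Temporal_Pole_Sup_R,Temporal,R,40,10
85,Temporal_Mid_L,Temporal,L,-46.7,12.3
86,Temporal_Mid_R,Temporal,R,46.7,12.3
87,Temporal_Pole_Mid_L,Temporal,L,-53.3,14.7
88,Temporal_Pole_Mid_R,Temporal,R,53.3,14.7
89,Temporal_Inf_L,Temporal,L,-60,17
90,Temporal_Inf_R,Temporal,R,60,17
91,Cerebellum_Crus1_L,Cerebellum,L,-20,-97
92,Cerebellum_Crus1_R,Cerebellum,R,20,-97
93,Cerebellum_Crus2_L,Cerebellum,L,-25,-95.2
94,Cerebellum_Crus2_R,Cerebellum,R,25,-95.2
95,Cerebellum_3_L,Cerebellum,L,-30,-93.5
96,Cerebellum_3_R,Cerebellum,R,30,-93.5
97,Cerebellum_4_5_L,Cerebellum,L,-35,-91.8
98,Cerebellum_4_5_R,Cerebellum,R,35,-91.8
99,Cerebellum_6_L,Cerebellum,L,-40,-90
100,Cerebellum_6_R,Cerebellum,R,40,-90
101,Cerebellum_7b_L,Cerebellum,L,-45,-88.2
102,Cerebellum_7b_R,Cerebellum,R,45,-88.2
103,Cerebellum_8_L,Cerebellum,L,-50,-86.5
104,Cerebellum_8_R,Cerebellum,R,50,-86.5
105,Cerebellum_9_L,Cerebellum,L,-55,-84.8
106,Cerebellum_9_R,Cerebellum,R,55,-84.8
107,Cerebellum_10_L,Cerebellum,L,-60,-83
108,Cerebellum_10_R,Cerebellum,R,60,-83
109,Vermis_1_2,Cerebellum,midline,0,-97
110,Vermis_3,Cerebellum,midline,0,-95
111,Vermis_4_5,Cerebellum,midline,0,-93
112,Vermis_6,Cerebellum,midline,0,-91
113,Vermis_7,Cerebellum,midline,0,-89
114,Vermis_8,Cerebellum,midline,0,-87
115,Vermis_9,Cerebellum,midline,0,-85
116,Vermis_10,Cerebellum,midline,0,-83
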