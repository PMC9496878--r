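# Best-effort nine-network assignment of the 90-region AAL parcellation.
# Odd rows are left-hemisphere, even rows right-hemisphere regions, in the
# standard atlas order. Edit freely: all computation is mapping-agnostic.
#index_base=1
index	label	network
1	Precentral_L	sensorimotor
2	Precentral_R	sensorimotor
3	Frontal_Sup_L	frontoparietal
4	Frontal_Sup_R	frontoparietal
5	Frontal_Sup_Orb_L	cingulo-opercular
6	Frontal_Sup_Orb_R	cingulo-opercular
7	Frontal_Mid_L	frontoparietal
8	Frontal_Mid_R	frontoparietal
9	Frontal_Mid_Orb_L	salience
10	Frontal_Mid_Orb_R	salience
11	Frontal_Inf_Oper_L	cingulo-opercular
12	Frontal_Inf_Oper_R	cingulo-opercular
13	Frontal_Inf_Tri_L	frontoparietal
14	Frontal_Inf_Tri_R	frontoparietal
15	Frontal_Inf_Orb_L	attention
16	Frontal_Inf_Orb_R	attention
17	Rolandic_Oper_L	sensorimotor
18	Rolandic_Oper_R	sensorimotor
19	Supp_Motor_Area_L	sensorimotor
20	Supp_Motor_Area_R	sensorimotor
21	Olfactory_L	salience
22	Olfactory_R	salience
23	Frontal_Sup_Medial_L	default-mode
24	Frontal_Sup_Medial_R	default-mode
25	Frontal_Med_Orb_L	default-mode
26	Frontal_Med_Orb_R	default-mode
27	Rectus_L	default-mode
28	Rectus_R	default-mode
29	Insula_L	salience
30	Insula_R	salience
31	Cingulum_Ant_L	default-mode
32	Cingulum_Ant_R	default-mode
33	Cingulum_Mid_L	cingulo-opercular
34	Cingulum_Mid_R	cingulo-opercular
35	Cingulum_Post_L	default-mode
36	Cingulum_Post_R	default-mode
37	Hippocampus_L	default-mode
38	Hippocampus_R	default-mode
39	ParaHippocampal_L	default-mode
40	ParaHippocampal_R	default-mode
41	Amygdala_L	salience
42	Amygdala_R	salience
43	Calcarine_L	visual
44	Calcarine_R	visual
45	Cuneus_L	visual
46	Cuneus_R	visual
47	Lingual_L	visual
48	Lingual_R	visual
49	Occipital_Sup_L	visual
50	Occipital_Sup_R	visual
51	Occipital_Mid_L	visual
52	Occipital_Mid_R	visual
53	Occipital_Inf_L	visual
54	Occipital_Inf_R	visual
55	Fusiform_L	visual
56	Fusiform_R	visual
57	Postcentral_L	sensorimotor
58	Postcentral_R	sensorimotor
59	Parietal_Sup_L	default-mode
60	Parietal_Sup_R	default-mode
61	Parietal_Inf_L	frontoparietal
62	Parietal_Inf_R	frontoparietal
63	SupraMarginal_L	attention
64	SupraMarginal_R	attention
65	Angular_L	default-mode
66	Angular_R	default-mode
67	Precuneus_L	default-mode
68	Precuneus_R	default-mode
69	Paracentral_Lobule_L	sensorimotor
70	Paracentral_Lobule_R	sensorimotor
71	Caudate_L	subcortical
72	Caudate_R	subcortical
73	Putamen_L	subcortical
74	Putamen_R	subcortical
75	Pallidum_L	subcortical
76	Pallidum_R	subcortical
77	Thalamus_L	subcortical
78	Thalamus_R	subcortical
79	Heschl_L	auditory
80	Heschl_R	auditory
81	Temporal_Sup_L	auditory
82	Temporal_Sup_R	auditory
83	Temporal_Pole_Sup_L	cingulo-opercular
84	Temporal_Pole_Sup_R	cingulo-opercular
85	Temporal_Mid_L	default-mode
86	Temporal_Mid_R	default-mode
87	Temporal_Pole_Mid_L	default-mode
88	Temporal_Pole_Mid_R	default-mode
89	Temporal_Inf_L	attention
90	Temporal_Inf_R	attention
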