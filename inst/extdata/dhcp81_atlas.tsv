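label_id	roi_name	hemisphere	tissue_class	homotopic_partner
1	Hippocampus_L	L	subcortical	Hippocampus_R
2	Hippocampus_R	R	subcortical	Hippocampus_L
3	Amygdala_L	L	subcortical	Amygdala_R
4	Amygdala_R	R	subcortical	Amygdala_L
5	Anterior_temporal_lobe_medial_GM_L	L	cGM	Anterior_temporal_lobe_medial_GM_R
6	Anterior_temporal_lobe_medial_GM_R	R	cGM	Anterior_temporal_lobe_medial_GM_L
7	Anterior_temporal_lobe_lateral_GM_L	L	cGM	Anterior_temporal_lobe_lateral_GM_R
8	Anterior_temporal_lobe_lateral_GM_R	R	cGM	Anterior_temporal_lobe_lateral_GM_L
9	Parahippocampal_gyrus_anterior_GM_L	L	cGM	Parahippocampal_gyrus_anterior_GM_R
10	Parahippocampal_gyrus_anterior_GM_R	R	cGM	Parahippocampal_gyrus_anterior_GM_L
11	Parahippocampal_gyrus_posterior_GM_L	L	cGM	Parahippocampal_gyrus_posterior_GM_R
12	Parahippocampal_gyrus_posterior_GM_R	R	cGM	Parahippocampal_gyrus_posterior_GM_L
13	Superior_temporal_gyrus_anterior_GM_L	L	cGM	Superior_temporal_gyrus_anterior_GM_R
14	Superior_temporal_gyrus_anterior_GM_R	R	cGM	Superior_temporal_gyrus_anterior_GM_L
15	Superior_temporal_gyrus_posterior_GM_L	L	cGM	Superior_temporal_gyrus_posterior_GM_R
16	Superior_temporal_gyrus_posterior_GM_R	R	cGM	Superior_temporal_gyrus_posterior_GM_L
17	Cerebellum_L	L	cerebellum	Cerebellum_R
18	Cerebellum_R	R	cerebellum	Cerebellum_L
19	Brainstem	U	brainstem	
20	Medial_inferior_temporal_gyri_anterior_GM_L	L	cGM	Medial_inferior_temporal_gyri_anterior_GM_R
21	Medial_inferior_temporal_gyri_anterior_GM_R	R	cGM	Medial_inferior_temporal_gyri_anterior_GM_L
22	Medial_inferior_temporal_gyri_posterior_GM_L	L	cGM	Medial_inferior_temporal_gyri_posterior_GM_R
23	Medial_inferior_temporal_gyri_posterior_GM_R	R	cGM	Medial_inferior_temporal_gyri_posterior_GM_L
24	Lateral_occipitotemporal_gyrus_anterior_GM_L	L	cGM	Lateral_occipitotemporal_gyrus_anterior_GM_R
25	Lateral_occipitotemporal_gyrus_anterior_GM_R	R	cGM	Lateral_occipitotemporal_gyrus_anterior_GM_L
26	Lateral_occipitotemporal_gyrus_posterior_GM_L	L	cGM	Lateral_occipitotemporal_gyrus_posterior_GM_R
27	Lateral_occipitotemporal_gyrus_posterior_GM_R	R	cGM	Lateral_occipitotemporal_gyrus_posterior_GM_L
28	Insula_GM_L	L	cGM	Insula_GM_R
29	Insula_GM_R	R	cGM	Insula_GM_L
30	Occipital_lobe_GM_L	L	cGM	Occipital_lobe_GM_R
31	Occipital_lobe_GM_R	R	cGM	Occipital_lobe_GM_L
32	Cingulate_gyrus_anterior_GM_L	L	cGM	Cingulate_gyrus_anterior_GM_R
33	Cingulate_gyrus_anterior_GM_R	R	cGM	Cingulate_gyrus_anterior_GM_L
34	Cingulate_gyrus_posterior_GM_L	L	cGM	Cingulate_gyrus_posterior_GM_R
35	Cingulate_gyrus_posterior_GM_R	R	cGM	Cingulate_gyrus_posterior_GM_L
36	Frontal_lobe_anterior_GM_L	L	cGM	Frontal_lobe_anterior_GM_R
37	Frontal_lobe_anterior_GM_R	R	cGM	Frontal_lobe_anterior_GM_L
38	Frontal_lobe_posterior_GM_L	L	cGM	Frontal_lobe_posterior_GM_R
39	Frontal_lobe_posterior_GM_R	R	cGM	Frontal_lobe_posterior_GM_L
40	Parietal_lobe_GM_L	L	cGM	Parietal_lobe_GM_R
41	Parietal_lobe_GM_R	R	cGM	Parietal_lobe_GM_L
42	Caudate_nucleus_L	L	subcortical	Caudate_nucleus_R
43	Caudate_nucleus_R	R	subcortical	Caudate_nucleus_L
44	Thalamus_L	L	subcortical	Thalamus_R
45	Thalamus_R	R	subcortical	Thalamus_L
46	Subthalamic_nucleus_L	L	subcortical	Subthalamic_nucleus_R
47	Subthalamic_nucleus_R	R	subcortical	Subthalamic_nucleus_L
51	Lentiform_nucleus_L	L	subcortical	Lentiform_nucleus_R
52	Lentiform_nucleus_R	R	subcortical	Lentiform_nucleus_L
53	Anterior_temporal_lobe_medial_WM_L	L	WM	Anterior_temporal_lobe_medial_WM_R
54	Anterior_temporal_lobe_medial_WM_R	R	WM	Anterior_temporal_lobe_medial_WM_L
55	Anterior_temporal_lobe_lateral_WM_L	L	WM	Anterior_temporal_lobe_lateral_WM_R
56	Anterior_temporal_lobe_lateral_WM_R	R	WM	Anterior_temporal_lobe_lateral_WM_L
57	Parahippocampal_gyrus_anterior_WM_L	L	WM	Parahippocampal_gyrus_anterior_WM_R
58	Parahippocampal_gyrus_anterior_WM_R	R	WM	Parahippocampal_gyrus_anterior_WM_L
59	Parahippocampal_gyrus_posterior_WM_L	L	WM	Parahippocampal_gyrus_posterior_WM_R
60	Parahippocampal_gyrus_posterior_WM_R	R	WM	Parahippocampal_gyrus_posterior_WM_L
61	Superior_temporal_gyrus_anterior_WM_L	L	WM	Superior_temporal_gyrus_anterior_WM_R
62	Superior_temporal_gyrus_anterior_WM_R	R	WM	Superior_temporal_gyrus_anterior_WM_L
63	Superior_temporal_gyrus_posterior_WM_L	L	WM	Superior_temporal_gyrus_posterior_WM_R
64	Superior_temporal_gyrus_posterior_WM_R	R	WM	Superior_temporal_gyrus_posterior_WM_L
65	Medial_inferior_temporal_gyri_anterior_WM_L	L	WM	Medial_inferior_temporal_gyri_anterior_WM_R
66	Medial_inferior_temporal_gyri_anterior_WM_R	R	WM	Medial_inferior_temporal_gyri_anterior_WM_L
67	Medial_inferior_temporal_gyri_posterior_WM_L	L	WM	Medial_inferior_temporal_gyri_posterior_WM_R
68	Medial_inferior_temporal_gyri_posterior_WM_R	R	WM	Medial_inferior_temporal_gyri_posterior_WM_L
69	Lateral_occipitotemporal_gyrus_anterior_WM_L	L	WM	Lateral_occipitotemporal_gyrus_anterior_WM_R
70	Lateral_occipitotemporal_gyrus_anterior_WM_R	R	WM	Lateral_occipitotemporal_gyrus_anterior_WM_L
71	Lateral_occipitotemporal_gyrus_posterior_WM_L	L	WM	Lateral_occipitotemporal_gyrus_posterior_WM_R
72	Lateral_occipitotemporal_gyrus_posterior_WM_R	R	WM	Lateral_occipitotemporal_gyrus_posterior_WM_L
73	Insula_WM_L	L	WM	Insula_WM_R
74	Insula_WM_R	R	WM	Insula_WM_L
75	Occipital_lobe_WM_L	L	WM	Occipital_lobe_WM_R
76	Occipital_lobe_WM_R	R	WM	Occipital_lobe_WM_L
77	Cingulate_gyrus_WM_L	L	WM	Cingulate_gyrus_WM_R
78	Cingulate_gyrus_WM_R	R	WM	Cingulate_gyrus_WM_L
79	Frontal_lobe_anterior_WM_L	L	WM	Frontal_lobe_anterior_WM_R
80	Frontal_lobe_anterior_WM_R	R	WM	Frontal_lobe_anterior_WM_L
81	Frontal_lobe_posterior_WM_L	L	WM	Frontal_lobe_posterior_WM_R
82	Frontal_lobe_posterior_WM_R	R	WM	Frontal_lobe_posterior_WM_L
86	Parietal_lobe_WM_L	L	WM	Parietal_lobe_WM_R
87	Parietal_lobe_WM_R	R	WM	Parietal_lobe_WM_L
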