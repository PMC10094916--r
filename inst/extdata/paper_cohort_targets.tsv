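patient_id	brightness_b	brightness_a	contrast_b	contrast_a	homogeneity_b	homogeneity_a	refl654_b	refl654_a
p01	106	134	4.8079	2.9964	0.8794	0.8049	746	866
p02	110	135	5.7381	5.2489	0.4298	0.5221	784	875
p03	120	153	4.9307	5.536	0.9024	0.679	787	938
p04	134	174	4.664	3.9747	0.446	0.7497	820	968
p05	139	154	6.2739	5.0443	0.4815	0.6739	832	918
p06	141	138	5.3304	5.1664	0.4538	0.5539	860	856
p07	142	164	5.3804	5.6348	0.5134	0.6365	848	955
p08	150	138	7.7515	6.3098	0.4711	0.6266	904	889
p09	160	165	6.97	6.1893	0.5125	0.4099	876	963
p10	163	157	6.5785	5.9809	0.5228	0.4768	910	926
p11	177	193	7.2945	6.4136	0.5296	0.7128	952	1012
p12	178	187	4.6001	4.0249	0.5777	0.834	915	984
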