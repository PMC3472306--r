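attribute	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT
twist_deg	30.515	30.53	35.198	36.266	34.472	38.506	37.343	36.78	30.286	33.957	33.646	34.349	39.368	31.573	32.604	39.052
tilt_deg	2.821	0.664	-0.403	0.444	-1.734	1.531	0.642	1.467	1.311	-1.199	-0.3	-2.089	0.581	-2.59	1.14	2.017
roll_deg	2.172	7.044	4.074	4.054	0.969	-0.077	0.9	4.028	0.27	5.094	0.792	6.398	1.19	9.61	8.03	6.779
shift_A	-0.134	0.032	0.05	0.228	-0.226	0.202	0.163	0.27	-0.167	-0.094	-0.252	0.14	0.26	0.054	-0.277	-0.029
slide_A	0.04	0.49	-0.481	-0.935	0.291	0.453	0.166	-0.193	0.653	0.544	-0.347	0.296	0.94	0.43	0.663	0.042
rise_A	3.423	3.207	3.143	3.18	3.245	3.41	3.134	3.498	3.312	3.414	3.377	3.105	3.337	3.109	3.392	3.405
twist_sd_deg	5.937	2.387	3.28	5.774	3.718	5.132	3.688	4.795	3.428	4.219	5.099	4.739	5.697	2.325	2.296	2.671
roll_sd_deg	6.039	3.95	3.583	5.008	3.29	6.493	6.627	4.631	3.96	6.491	5.854	3.476	4.759	4.611	3.207	5.407
slide_sd_A	0.51	0.583	0.872	0.605	0.474	0.457	0.437	0.888	0.862	0.611	0.335	0.863	0.749	0.737	0.444	0.879
propeller_twist_deg	-13.559	-14.334	-12.878	-16.262	-14.494	-12.711	-17.514	-9.091	-10.586	-13.411	-11.671	-17.564	-10.0	-16.665	-14.59	-12.48
helical_repeat_bp	10.483	10.564	10.55	10.636	10.068	10.005	10.249	10.278	10.167	10.431	10.627	10.135	10.774	10.718	10.159	10.708
minor_groove_width_A	4.554	6.938	7.293	6.092	6.33	6.777	6.044	5.511	7.035	7.331	6.677	5.803	4.963	6.938	5.96	6.729
minor_groove_depth_A	8.782	8.92	9.438	8.939	9.025	8.778	9.268	8.858	8.636	8.995	9.171	9.147	9.45	9.421	9.279	9.282
major_groove_width_A	12.142	10.906	11.05	10.808	10.658	11.67	12.072	12.487	11.265	11.232	12.149	11.263	10.511	12.135	10.997	10.894
major_groove_depth_A	8.707	9.119	9.312	8.583	8.677	8.046	9.486	8.424	9.044	9.45	8.672	9.406	9.178	8.681	8.423	8.676
stacking_energy_kcal	-11.862	-10.049	-11.155	-11.68	-9.272	-11.589	-10.093	-10.304	-11.485	-9.419	-14.253	-11.878	-14.04	-15.103	-5.321	-6.552
duplex_dG37_kcal	-1.11	-1.181	-1.165	-0.515	-1.496	-2.14	-1.535	-0.887	-1.932	-1.421	-1.967	-1.65	-2.274	-1.165	-1.057	-1.003
duplex_dH_kcal	-7.558	-7.657	-7.484	-8.284	-6.894	-9.091	-7.333	-8.639	-6.815	-8.264	-10.353	-7.102	-8.297	-7.602	-6.114	-7.728
duplex_dS_cal	-23.649	-25.97	-20.505	-18.634	-16.624	-19.864	-16.563	-19.195	-22.233	-26.163	-25.025	-23.979	-23.878	-25.076	-21.422	-24.093
melting_temp_C	61.386	56.55	91.825	39.514	72.638	49.703	82.501	43.661	46.583	84.775	92.353	85.276	68.33	65.72	71.033	27.551
bendability	0.205	-0.063	0.069	0.152	0.055	0.067	-0.199	0.253	-0.21	0.186	0.083	0.028	-0.032	-0.259	-0.008	-0.199
bending_stiffness	83.326	46.648	27.481	124.141	85.551	66.271	57.858	67.243	56.863	120.2	53.78	47.95	63.379	21.13	70.526	27.664
a_philicity	0.216	0.122	0.37	0.334	-0.016	0.227	0.172	0.37	0.094	0.155	-0.159	0.255	-0.04	0.343	-0.011	-0.154
b_dna_propensity	0.011	0.14	0.136	0.136	0.126	0.127	0.102	0.147	0.154	0.061	0.032	-0.066	-0.034	0.196	0.152	0.094
z_dna_energy_kcal	4.13	2.744	2.051	5.546	6.28	6.455	4.73	3.156	1.001	3.863	7.172	3.434	1.037	6.109	5.744	5.103
protein_deformability	8.913	12.999	6.746	11.86	7.395	9.284	6.958	11.622	8.492	7.028	2.764	9.698	1.363	6.54	11.085	5.343
dna_denaturation	1.422	0.697	0.756	0.731	0.75	0.679	1.18	0.741	0.942	1.263	0.731	1.147	1.425	0.708	0.658	0.862
dnase_sensitivity	0.572	0.122	0.278	0.332	-0.312	0.231	0.223	0.005	0.494	0.201	-0.49	-0.369	-0.15	0.327	-0.261	0.436
nucleosome_positioning	0.175	-0.164	0.142	-0.218	-0.141	-0.356	0.0	0.37	0.195	-0.101	0.161	-0.271	-0.21	-0.223	-0.015	0.132
persistence_length_nm	54.863	58.588	44.254	43.652	47.225	58.99	58.2	40.308	45.9	53.391	57.727	54.967	44.314	50.123	45.789	46.043
flexibility_shift	9.568	1.461	7.234	11.192	7.451	5.582	6.127	2.25	4.399	6.393	11.118	7.704	4.445	4.795	7.913	5.131
flexibility_slide	3.911	2.069	8.831	8.958	8.17	4.903	8.198	6.673	6.867	10.194	4.512	10.712	7.622	5.966	5.477	11.962
entropy_cal	-27.092	-20.751	-21.778	-23.725	-25.532	-21.684	-27.108	-28.54	-18.862	-29.361	-21.414	-29.346	-23.669	-25.628	-25.51	-25.344
enthalpy_kcal	-10.472	-5.332	-7.028	-9.235	-8.659	-9.939	-8.673	-10.574	-5.395	-5.457	-10.51	-9.381	-10.446	-10.219	-9.89	-8.159
free_energy_kcal	-1.619	-0.836	-0.667	-1.962	-1.912	-1.963	-0.785	-1.086	-2.182	-1.955	-1.789	-2.129	-1.609	-2.237	-0.9	-1.824
ionic_energy	1.167	0.583	1.168	0.718	1.805	1.051	0.84	0.828	1.86	0.537	1.296	1.635	1.961	1.418	1.866	1.267
hydrophilicity	0.852	0.368	0.765	0.376	0.798	0.724	0.85	0.611	0.523	0.922	0.916	0.334	0.697	0.332	0.561	0.963
polarizability	2.819	4.173	4.495	4.556	3.243	4.266	4.847	4.329	4.279	3.866	3.327	4.568	3.601	3.997	4.647	4.672
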