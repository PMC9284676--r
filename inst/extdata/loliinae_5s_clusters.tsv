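sample	ploidy	n_reads	genome_proportion	repeat_size_bp	kmer_coverage	connected_component_index	shape_type
Festuca_abyssinica	4	180	0.036	316	0.885	0.967	1
Festuca_africana	10	214	0.043	317	0.488	0.879	2
Festuca_amplissima	6	158	0.032	318	0.744	0.994	1
Festuca_a_arundinacea	6	369	0.074	315	0.78	0.987	1
Festuca_a_letourneuxiana	10	532	0.11	307	0.721	0.974	2
Festuca_a_atlantigena	8	428	0.086	307	0.791	0.981	2
Festuca_asplundii	6	110	0.022	318	0.894	0.982	1
Festuca_caldasii	4	NA	NA	NA	NA	NA	NA
Festuca_capillifolia	2	340	0.068	318	0.9	0.976	1
Festuca_chimborazensis	6	179	0.036	319	0.845	0.899	2
Festuca_dracomontana	NA	629	0.13	307	0.75	0.936	1
Festuca_durandoi	2	520	0.1	318	0.812	0.994	2
Festuca_eskia	2	525	0.1	319	0.873	0.989	2
Festuca_fenas	4	222	0.044	307	0.781	0.973	1
Festuca_fimbriata	6	104	0.021	317	0.8	0.923	1
Festuca_fontqueri	2	470	0.094	296	0.824	0.977	2
Festuca_francoi	2	632	0.13	317	0.748	0.981	2
Festuca_gigantea	6	NA	NA	NA	NA	NA	NA
Festuca_gracillima	6	NA	NA	NA	NA	NA	NA
Festuca_gudoschnikovii	4	NA	NA	NA	NA	NA	NA
Festuca_holubii	NA	179	0.036	318	0.863	0.944	2
Festuca_lasto	2	470	0.094	296	0.824	0.977	1
Festuca_mairei	4	330	0.066	315	0.791	0.921	1
Festuca_mekiste	NA	109	0.022	317	0.619	0.917	1
Festuca_molokaiensis	NA	208	0.042	316	0.666	0.861	2
Festuca_ovina	2	331	0.066	316	0.952	0.985	1
Festuca_pampeana	8	402	0.08	317	0.812	0.98	1
Festuca_paniculata	2	269	0.054	318	0.781	0.978	2
Festuca_parvigluma	4	190	0.038	316	0.711	0.884	1
Festuca_pratensis	2	447	0.089	545	0.832	0.911	2
Festuca_procera	4	165	0.033	317	0.863	0.976	2
Festuca_pyrenaica	4	204	0.041	316	0.62	0.941	2
Festuca_pyrogea	NA	850	0.17	326	0.602	0.955	2
Festuca_rubra	6	338	0.068	316	0.737	0.87	2
Festuca_scabra	4	232	0.046	301	0.782	0.978	2
Festuca_simensis	4	412	0.082	296	0.675	0.951	2
Festuca_spectabilis	6	1128	0.23	316	0.791	0.99	2
Festuca_superba	8	184	0.037	316	0.772	0.995	1
Festuca_triflora	2	217	0.043	262	0.498	0.982	2
Lolium_canariense	2	306	0.061	294	0.842	0.974	1
Lolium_perenne	2	447	0.089	307	0.868	0.982	1
Lolium_persicum	2	1154	0.23	307	0.832	0.976	1
Lolium_rigidum	2	892	0.18	307	0.809	0.983	1
Lolium_saxatile	2	157	0.031	308	0.914	0.975	2
Megalachne_masafuerana	NA	690	0.14	224	0.438	0.997	2
Micropyropsis_tuberosa	2	911	0.18	307	0.865	0.98	1
Vulpia_ciliata	4	414	0.083	315	0.916	0.993	2
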