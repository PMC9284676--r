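sample	group	ploidy	c2_pg	cx1_pg	cx1_mbp
Festuca_africana	BL	10	NA	NA	NA
Festuca_amplissima	BL	6	NA	NA	NA
Festuca_caldasii	BL	4	20.36	5.09	4978.02
Festuca_durandoi	BL	2	NA	3.66	3584.86
Festuca_lasto	BL	2	NA	NA	NA
Festuca_mekiste	BL	NA	NA	NA	NA
Festuca_molokaiensis	BL	NA	NA	NA	NA
Festuca_paniculata	BL	2	7.65	3.83	3740.85
Festuca_parvigluma	BL	4	NA	NA	NA
Festuca_scabra	BL	4	NA	NA	NA
Festuca_spectabilis	BL	6	NA	NA	NA
Festuca_superba	BL	8	NA	NA	NA
Festuca_triflora	BL	2	7.84	3.92	3833.76
Festuca_abyssinica	FL	4	NA	NA	NA
Festuca_asplundii	FL	6	21.23	3.54	3460.49
Festuca_capillifolia	FL	2	NA	NA	NA
Festuca_chimborazensis	FL	6	13.48	2.25	2197.24
Festuca_eskia	FL	2	5.7	2.85	2787.3
Festuca_fimbriata	FL	6	NA	NA	NA
Festuca_francoi	FL	2	NA	NA	NA
Festuca_gracillima	FL	6	NA	NA	NA
Festuca_holubii	FL	NA	NA	NA	NA
Festuca_ovina	FL	2	4.82	2.41	2356.98
Festuca_pampeana	FL	8	NA	NA	NA
Festuca_procera	FL	4	14.88	3.72	3638.16
Festuca_pyrenaica	FL	4	NA	NA	NA
Festuca_pyrogea	FL	NA	NA	NA	NA
Festuca_rubra	FL	6	13.68	2.28	2229.84
Megalachne_masafuerana	FL	NA	NA	NA	NA
Vulpia_ciliata	FL	4	8.28	2.07	2024.46
Festuca_a_arundinacea	Sch	6	17.46	2.91	2845.98
Festuca_a_atlantigena	Sch	8	16.22	2.03	1982.895
Festuca_a_letourneuxiana	Sch	10	19.7	1.97	1926.66
Festuca_dracomontana	Sch	NA	NA	NA	NA
Festuca_fenas	Sch	4	10.48	2.62	2562.36
Festuca_fontqueri	Sch	2	5.54	2.77	2709.06
Festuca_gigantea	Sch	6	20.75	3.46	3382.25
Festuca_gudoschnikovii	Sch	4	NA	NA	NA
Festuca_mairei	Sch	4	10.04	2.51	2454.78
Festuca_pratensis	Sch	2	6.5	3.25	3178.5
Festuca_simensis	Sch	4	NA	NA	NA
Lolium_canariense	Sch	2	4.3	2.15	2102.7
Lolium_perenne	Sch	2	5.51	2.76	2694.39
Lolium_persicum	Sch	2	6.4	3.2	3129.6
Lolium_rigidum	Sch	2	5.49	2.75	2684.61
Lolium_saxatile	Sch	2	NA	NA	NA
Micropyropsis_tuberosa	Sch	2	NA	NA	NA
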