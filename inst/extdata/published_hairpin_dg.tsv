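direction	mode	precursor_id	ns	nn	dg_natural	dg_corrected
to_reference	sexual	bsex-MIR156a	U/A	75	-21.6	-19.3
to_reference	sexual	bsex-MIR157a	U/A	75	-21.6	-19.3
to_reference	sexual	bsex-MIR396	U/G	143	-55.9	-56.8
to_reference	sexual	bsex-MIR400	A/G	76	-12.0	-11.7
to_reference	sexual	bsex-MIR403	G/C	75	-18.7	-15.5
to_reference	sexual	bsex-MIR414.1	U/A,A/G	170	-49.8	-48.2
to_reference	sexual	bsex-MIR414.2	U/A	221	-52.2	-56.4
to_reference	sexual	bsex-MIR414.3	U/A	233	-57.9	-60.0
to_reference	sexual	bsex-MIR852	U/G	89	-34.1	-34.7
to_reference	apomictic	bapo-MIR156a.1	U/A	66	-19.8	-15.6
to_reference	apomictic	bapo-MIR156a.2	U/A	105	-27.9	-26.7
to_reference	apomictic	bapo-MIR157m	A/G	119	-38.2	-31.3
to_reference	apomictic	bapo-MIR394a	C/A	126	-23.8	-26.2
to_reference	apomictic	bapo-MIR414.1	U/A,A/U	208	-35.2	-34.2
to_reference	apomictic	bapo-MIR414.2	U/A,A/G	170	-49.8	-48.2
to_reference	apomictic	bapo-MIR414.3	U/G	104	-30.5	-29.2
to_reference	apomictic	bapo-MIR415	A/G,C/A	135	-33.8	-30.3
to_reference	apomictic	bapo-MIR861	A/G,G/U	233	-79.4	-71.4
to_observed	reference	ath-MIR156a	U/A	123	-57.1	-52.4
to_observed	reference	ath-MIR157m	A/G	50	-10.2	-9.3
to_observed	reference	ath-MIR394	C/A	117	-53.1	-46.6
to_observed	reference	osa-MIR396	U/G	154	-64.7	-60.1
to_observed	reference	ath-MIR400	A/U	102	-38.4	-34.3
to_observed	reference	ath-MIR403	G/C	135	-38.8	-35.4
to_observed	reference	ath-MIR414.1	U/A,A/G	108	-22.0	-22.3
to_observed	reference	ath-MIR414.2	U/G	108	-22.0	-21.8
to_observed	reference	ath-MIR414.3	U/A,A/U	108	-22.0	-26.4
to_observed	reference	ath-MIR414.4	U/A	108	-22.0	-23.3
to_observed	reference	ath-MIR414.5	U/A,A/G,A/G	108	-22.0	-22.4
to_observed	reference	ath-MIR415	A/G,C/A	110	-27.0	-24.8
to_observed	reference	ath-MIR852	U/G	202	-80.6	-80.8
to_observed	reference	ath-MIR861	A/G,G/U	132	-56.3	-51.6
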