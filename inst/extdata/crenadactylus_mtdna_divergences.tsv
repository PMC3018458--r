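# Crenadactylus pairwise mitochondrial (ND2) divergences between the 10
# candidate taxa: uncorrected p-distances (upper triangle) and
# model-corrected distances (lower triangle), with per-taxon sequence
# sample sizes, transcribed from the published divergence table.
taxon	N	1	2	3	4	5	6	7	8	9	10
1. South-west	7	_	0.235	0.183	0.212	0.219	0.256	0.217	0.245	0.239	0.222
2. Cape Range	4	0.623	_	0.201	0.246	0.254	0.289	0.255	0.264	0.262	0.267
3. Carnarvon	10	0.359	0.456	_	0.205	0.205	0.243	0.220	0.240	0.232	0.225
4. Pilbara	10	0.505	0.709	0.494	_	0.171	0.206	0.192	0.209	0.199	0.185
5. Central Ranges	11	0.512	0.718	0.457	0.294	_	0.203	0.202	0.221	0.217	0.207
6. Kimberley A	1	0.704	1.059	0.673	0.445	0.415	_	0.191	0.174	0.153	0.153
7. Kimberley B	1	0.557	0.872	0.577	0.421	0.443	0.347	_	0.181	0.174	0.153
8. Kimberley C	2	0.657	0.923	0.698	0.470	0.491	0.281	0.333	_	0.161	0.165
9. Kimberley D	1	0.680	0.981	0.686	0.463	0.504	0.221	0.326	0.266	_	0.139
10. Kimberley E	7	0.615	0.997	0.636	0.405	0.479	0.248	0.281	0.281	0.227	_
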