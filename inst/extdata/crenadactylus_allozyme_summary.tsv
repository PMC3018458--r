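# Crenadactylus allozyme summary over the 10 candidate taxa:
# fixed-difference counts with display percentages (lower triangle) and
# Nei unbiased genetic distances (upper triangle), transcribed from the
# published summary table.
taxon	1	2	3	4	5	6	7	8	9	10
1. South-West	-	0.304	0.355	0.619	0.560	0.657	0.640	0.542	0.623	0.447
2. Carnarvon Basin	10 (24%)	-	0.446	0.794	0.572	0.728	0.810	0.597	0.740	0.531
3. Cape Range	9 (21%)	13 (31%)	-	0.700	0.593	0.557	0.629	0.591	0.607	0.637
4. Pilbara	18 (43%)	21 (50%)	20 (48%)	-	0.439	0.386	0.479	0.491	0.498	0.574
5. Kimberley A	18 (44%)	18 (44%)	17 (41%)	13 (32%)	-	0.194	0.404	0.253	0.314	0.534
6. Kimberley B	20 (48%)	22 (52%)	15 (36%)	13 (31%)	7 (17%)	-	0.368	0.414	0.435	0.593
7. Kimberley C	20 (48%)	22 (52%)	18 (43%)	16 (38%)	14 (34%)	11 (26%)	-	0.321	0.262	0.689
8. Kimberley D	16 (39%)	17 (41%)	17 (41%)	16 (39%)	9 (22%)	13 (32%)	12 (29%)	-	0.120	0.525
9. Kimberley E	18 (43%)	21 (50%)	16 (38%)	16 (38%)	10 (24%)	12 (29%)	8 (19%)	4 (10%)	-	0.575
10. Central Ranges	15 (36%)	17 (40%)	17 (40%)	16 (38%)	16 (39%)	19 (45%)	20 (48%)	16 (39%)	17 (40%)	-
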