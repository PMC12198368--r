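chrM_synth	0	100	leader_H	0	+	leader
chrM_synth	100	170	mtF	0	+	tRNA
chrM_synth	170	1120	rnS	0	+	rRNA
chrM_synth	1120	1190	mtV	0	+	tRNA
chrM_synth	1190	2750	rnL	0	+	rRNA
chrM_synth	2750	2820	mtL1	0	+	tRNA
chrM_synth	2820	3780	mtNd1	0	+	mRNA
chrM_synth	3780	3850	mtI	0	+	tRNA
chrM_synth	3850	4890	mtNd2	0	+	mRNA
chrM_synth	4890	4960	mtW	0	+	tRNA
chrM_synth	4960	5030	mtA	0	-	tRNA
chrM_synth	5030	5100	mtN	0	-	tRNA
chrM_synth	5100	5170	mtC	0	-	tRNA
chrM_synth	5170	5240	mtY	0	-	tRNA
chrM_synth	5240	6780	mtCo1	0	+	mRNA
chrM_synth	6780	6850	mtD	0	+	tRNA
chrM_synth	6850	7530	mtCo2	0	+	mRNA
chrM_synth	7530	7600	mtK	0	+	tRNA
chrM_synth	7600	7810	mtAtp8	0	+	mRNA
chrM_synth	7770	8440	mtAtp6	0	+	mRNA
chrM_synth	8440	9000	mtCo3	0	+	mRNA
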