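# Published per-variant and gene-level evidence for the eight intestinal
# brush-border carbohydrate genes scanned in YRI/CEU/CHBJPT (the lactase
# locus is excluded). Ranks are empirical percentile ranks against the
# control gene set; "greater than 0.999" entries are encoded as 0.9995.
# Rows with sub-threshold ranks are retained so that non-candidate genes
# exercise the decision rules non-trivially.
gene	type	snp	population	pair	stat	rank
SI	dind	rs41273563	YRI	NA	NA	0.97
SI	dind	rs11919067	YRI	NA	NA	0.9995
SI	dind	rs112446029	YRI	NA	NA	0.99
SI	dind	rs6788812	YRI	NA	NA	0.98
SI	dind	rs6788812	CHBJPT	NA	NA	0.98
SI	fst	rs41273563	NA	YRI/CHBJPT	NA	0.96
SI	fst	rs6788812	NA	YRI/CEU	NA	0.95
SI	gene_stat	NA	YRI	NA	pi	0.21
TREH	dind	rs527619	YRI	NA	NA	0.98
TREH	dind	rs527619	CEU	NA	NA	0.97
TREH	dind	rs527619	CHBJPT	NA	NA	0.99
TREH	gene_stat	NA	YRI	NA	tajimas_d	0.35
SLC5A1	dind	rs117628874	CEU	NA	NA	0.95
SLC5A1	dind	rs74399071	CEU	NA	NA	0.96
SLC5A1	dind	rs79022443	CEU	NA	NA	0.97
SLC5A1	dind	rs78578916	CEU	NA	NA	0.98
SLC5A1	dind	rs2899174	CEU	NA	NA	0.95
SLC5A1	gene_stat	NA	CHBJPT	NA	pi	0.03
SLC5A1	gene_stat	NA	CEU	NA	tajimas_d	0.04
SLC5A1	gene_stat	NA	CHBJPT	NA	tajimas_d	0.04
SLC2A2	dind	rs11720640	CHBJPT	NA	NA	0.99
SLC2A2	dind	rs1905504	CHBJPT	NA	NA	0.9995
SLC2A2	dind	rs7635100	CHBJPT	NA	NA	0.9995
SLC2A2	dind	rs6780208	CHBJPT	NA	NA	0.9995
SLC2A2	dind	rs78425790	YRI	NA	NA	0.97
SLC2A2	dind	rs7649712	YRI	NA	NA	0.98
SLC2A2	dind	rs75513459	YRI	NA	NA	0.97
SLC2A2	dind	rs79438006	YRI	NA	NA	0.96
SLC2A2	dind	rs75975268	YRI	NA	NA	0.97
SLC2A2	dind	rs74828611	YRI	NA	NA	0.98
SLC2A2	fst	rs11720640	NA	YRI/CHBJPT	NA	0.95
SLC2A2	fst	rs1905504	NA	YRI/CHBJPT	NA	0.95
SLC2A2	fst	rs7635100	NA	YRI/CHBJPT	NA	0.95
SLC2A2	fst	rs6780208	NA	YRI/CHBJPT	NA	0.95
SLC2A2	fst	rs78425790	NA	YRI/CEU	NA	0.99
SLC2A2	fst	rs78425790	NA	YRI/CHBJPT	NA	0.99
SLC2A2	fst	rs7649712	NA	YRI/CEU	NA	0.99
SLC2A2	fst	rs7649712	NA	YRI/CHBJPT	NA	0.99
SLC2A2	fst	rs75513459	NA	YRI/CEU	NA	0.99
SLC2A2	fst	rs75513459	NA	YRI/CHBJPT	NA	0.99
SLC2A2	fst	rs79438006	NA	YRI/CEU	NA	0.99
SLC2A2	fst	rs79438006	NA	YRI/CHBJPT	NA	0.99
SLC2A2	fst	rs75975268	NA	YRI/CEU	NA	0.99
SLC2A2	fst	rs75975268	NA	YRI/CHBJPT	NA	0.99
SLC2A2	fst	rs74828611	NA	YRI/CEU	NA	0.99
SLC2A2	fst	rs74828611	NA	YRI/CHBJPT	NA	0.99
SLC2A2	gene_stat	NA	CHBJPT	NA	tajimas_d	0.04
SLC2A5	dind	rs875996	CEU	NA	NA	0.97
SLC2A5	dind	rs34605482	CEU	NA	NA	0.95
SLC2A5	fst	rs875996	NA	YRI/CEU	NA	0.99
SLC2A5	fst	rs34605482	NA	YRI/CEU	NA	0.99
SLC2A5	gene_stat	NA	CEU	NA	pi	0.44
MGAM	dind	mgam_v1	YRI	NA	NA	0.62
MGAM	dind	mgam_v2	CEU	NA	NA	0.41
MGAM	fst	mgam_v1	NA	YRI/CEU	NA	0.71
MGAM	gene_stat	NA	YRI	NA	pi	0.40
MGAM	gene_stat	NA	CEU	NA	tajimas_d	0.58
TAS1R2	dind	tas1r2_v1	CHBJPT	NA	NA	0.88
TAS1R2	fst	tas1r2_v1	NA	YRI/CHBJPT	NA	0.66
TAS1R2	gene_stat	NA	CEU	NA	tajimas_d	0.50
TAS1R3	dind	tas1r3_v1	YRI	NA	NA	0.23
TAS1R3	gene_stat	NA	CHBJPT	NA	theta_w	0.60
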