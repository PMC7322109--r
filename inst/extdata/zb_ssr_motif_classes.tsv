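# Canonical-class locus counts from the G-SSR motif distribution table of a
# Zanthoxylum bungeanum genome survey (57288 scaffolds >= 1 kb, 27153 loci).
# Columns: type (mono..hexa), class (canonical motif class or "Others"), count.
type	class	count
mono	A/T	19393
mono	C/G	313
di	AT/AT	3214
di	AG/CT	1028
di	AC/GT	905
di	CG/CG	7
tri	AAT/ATT	1021
tri	AAG/CTT	376
tri	ATC/GAT	143
tri	AAC/GTT	83
tri	ACC/GGT	76
tri	AGG/CCT	63
tri	AGC/GCT	46
tri	CCG/CGG	18
tri	ACT/AGT	18
tri	ACG/CGT	16
tetra	AAAT/ATTT	159
tetra	ACAT/ATGT	43
tetra	AAAG/CTTT	32
tetra	AATT/AATT	32
tetra	AAAC/GTTT	23
tetra	Others	20
penta	AAAAT/ATTTT	27
penta	AAAAC/GTTTT	8
penta	AAATT/AATTT	4
penta	AATCG/ATTCG	4
penta	Others	17
hexa	AAAAAT/ATTTTT	10
hexa	AAAAAC/GTTTTT	6
hexa	AAATAT/ATATTT	4
hexa	AAAAAG/CTTTTT	3
hexa	Others	41
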