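##gff-version 3
# Synthetic genome-slice segment (grape-like): shares 12 families with the
# coffee-like fixture, one inverted (f04), plus two segment-specific genes.
grape_chr4	synmapr	gene	1000	1500	.	+	.	ID=gv_g01;family=f01
grape_chr4	synmapr	gene	3000	3500	.	+	.	ID=gv_g02;family=f02
grape_chr4	synmapr	gene	5000	5500	.	+	.	ID=gv_g03;family=f03
grape_chr4	synmapr	gene	7000	7500	.	-	.	ID=gv_g04;family=f04
grape_chr4	synmapr	gene	9000	9500	.	+	.	ID=gv_g05;family=f05
grape_chr4	synmapr	gene	11000	11500	.	+	.	ID=gv_g06
grape_chr4	synmapr	gene	13000	13500	.	+	.	ID=gv_g07;family=f06
grape_chr4	synmapr	gene	15000	15500	.	+	.	ID=gv_g08;family=f07
grape_chr4	synmapr	gene	17000	17500	.	+	.	ID=gv_g09;family=f08
grape_chr4	synmapr	gene	19000	19500	.	+	.	ID=gv_g10;family=f09
grape_chr4	synmapr	gene	21000	21500	.	+	.	ID=gv_g11;family=f10
grape_chr4	synmapr	gene	23000	23500	.	-	.	ID=gv_g12
grape_chr4	synmapr	gene	25000	25500	.	+	.	ID=gv_g13;family=f11
grape_chr4	synmapr	gene	27000	27500	.	+	.	ID=gv_g14;family=f12
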