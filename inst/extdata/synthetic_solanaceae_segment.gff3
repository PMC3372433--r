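##gff-version 3
# Synthetic BAC-scale segment (Solanaceae-like): shares 8 families with the
# coffee-like fixture, two inverted (f02, f03), one tandem duplicate of f06,
# two families absent from the coffee fixture and one unlabelled gene.
tomato_bac	synmapr	gene	1000	1500	.	+	.	ID=tm_g01;family=f01
tomato_bac	synmapr	gene	3000	3500	.	-	.	ID=tm_g02;family=f02
tomato_bac	synmapr	gene	5000	5500	.	-	.	ID=tm_g03;family=f03
tomato_bac	synmapr	gene	7000	7500	.	+	.	ID=tm_g04;family=f13
tomato_bac	synmapr	gene	9000	9500	.	+	.	ID=tm_g05;family=f05
tomato_bac	synmapr	gene	11000	11500	.	+	.	ID=tm_g06;family=f06
tomato_bac	synmapr	gene	13000	13500	.	+	.	ID=tm_g07;family=f06
tomato_bac	synmapr	gene	15000	15500	.	-	.	ID=tm_g08;family=f14
tomato_bac	synmapr	gene	17000	17500	.	+	.	ID=tm_g09;family=f09
tomato_bac	synmapr	gene	19000	19500	.	+	.	ID=tm_g10;family=f10
tomato_bac	synmapr	gene	21000	21500	.	+	.	ID=tm_g11
tomato_bac	synmapr	gene	23000	23500	.	+	.	ID=tm_g12;family=f12
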