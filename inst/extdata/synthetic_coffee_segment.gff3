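##gff-version 3
# Synthetic BAC-scale segment (coffee-like) for microsynteny examples/tests.
# Family labels are fixture-defined; family f06 plays the fruit-shape anchor.
coffee_bac	synmapr	gene	1000	1500	.	+	.	ID=cf_g01;family=f01
coffee_bac	synmapr	gene	3000	3500	.	+	.	ID=cf_g02;family=f02
coffee_bac	synmapr	gene	5000	5500	.	+	.	ID=cf_g03;family=f03
coffee_bac	synmapr	gene	7000	7500	.	+	.	ID=cf_g04;family=f04
coffee_bac	synmapr	gene	9000	9500	.	+	.	ID=cf_g05
coffee_bac	synmapr	gene	11000	11500	.	+	.	ID=cf_g06;family=f05
coffee_bac	synmapr	gene	13000	13500	.	+	.	ID=cf_g07;family=f06
coffee_bac	synmapr	gene	15000	15500	.	+	.	ID=cf_g08;family=f07
coffee_bac	synmapr	gene	17000	17500	.	+	.	ID=cf_g09;family=f08
coffee_bac	synmapr	gene	19000	19500	.	-	.	ID=cf_g10
coffee_bac	synmapr	gene	21000	21500	.	+	.	ID=cf_g11;family=f09
coffee_bac	synmapr	gene	23000	23500	.	+	.	ID=cf_g12;family=f10
coffee_bac	synmapr	gene	25000	25500	.	+	.	ID=cf_g13;family=f11
coffee_bac	synmapr	gene	27000	27500	.	+	.	ID=cf_g14;family=f12
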