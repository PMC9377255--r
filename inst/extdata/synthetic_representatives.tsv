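id	gus_class	taxonomy	catalytic	loop1_start	loop1_end	loop2_start	loop2_end	fmn_start	fmn_end
synthRep01_L1	L1	Bacteroides simulans	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	358	419	420	.	.
synthRep02_L1	L1	Bacteroides fictus	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	358	419	420	.	.
synthRep03_L1	L1	Phocaeicola modelli	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	358	419	420	.	.
synthRep04_L1	L1	Parabacteroides exemplar	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	358	419	420	.	.
synthRep05_mL1	mL1	Lactobacillus artificialis	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	348	409	410	.	.
synthRep06_mL1	mL1	Blautia synthetica	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	348	409	410	.	.
synthRep07_mL1	mL1	Roseburia imitata	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	348	409	410	.	.
synthRep08_L2	L2	Bacteroides simulans	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	418	.	.
synthRep09_L2	L2	Alistipes confectus	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	418	.	.
synthRep10_mL2	mL2	Clostridium fabricatum	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	410	.	.
synthRep11_mL2	mL2	Eubacterium simulatum	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	410	.	.
synthRep12_mL1_2	mL1_2	Dorea conficta	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	348	409	416	.	.
synthRep13_NL	NL	Faecalibacterium fictum	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	404	.	.
synthRep14_NL	NL	Ruminococcus artifex	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	404	.	.
synthRep15_NL	NL	Coprococcus exemplaris	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	404	.	.
synthRep16_FMN	FMN	Roseburia imitata	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	404	445	504
synthRep17_FMN	FMN	Faecalibacterium fictum	160:N,162:K,205:Y,248:E,310:E,330:N,338:H	341	342	403	404	445	504
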