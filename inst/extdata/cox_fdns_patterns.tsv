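gene	branch	template_site	states	query_site	proximity	severity	chem_label	syn_observed
COX1	D	29	VLVVVLLLLL	36	within13	low	nonpolar-nonpolar	yes
COX1	D	35	LLLNNMMMMM	42	within4	low	nonpolar-nonpolar	yes
COX1	D	39	AALLLFFFFF	46	within4	low	nonpolar-nonpolar	yes
COX1	D	46	TNFFFYYYYY	53	within13	high	nonpolar-polar	no
COX1	D	215	LLLLLIIIII	221	unflagged	low	nonpolar-nonpolar	no
COX1	D	462	LLTNNVVVVV	468	within4	high	polar-nonpolar	yes
COX1	D	464	AAGGGSSSSS	470	within4	high	nonpolar-polar	yes
COX1	D	479	KKYYYFFFFF	485	within13	high	polar-nonpolar	yes
COX1	C	89	AAAAAASSSS	96	within13	high	nonpolar-polar	no
COX1	C	259	TTLIILMMMM	265	within4	low	nonpolar-nonpolar	no
COX1	C	270	YYASSSTTTT	276	within13	low	polar-polar	no
COX1	C	353	LILLLLIIII	359	within13	low	nonpolar-nonpolar	no
COX1	C	399	LLFFFLYYYY	405	within4	high	nonpolar-polar	no
COX1	C	403	YYYVVFLLLL	409	within13	low	nonpolar-nonpolar	no
COX1	C	441	SSLLLLMMMM	447	within13	low	nonpolar-nonpolar	yes
COX1	C	494	WWYVVNGGGG	500	within4	medium	polar-nonpolar	yes
COX1	C	495	LLCVAMSSSS	501	within13	high	nonpolar-polar	no
COX1	B	476	FFFFFFFMMM	482	within13	low	nonpolar-nonpolar	yes
COX2	C	94	SSNFYNQQQQ	97	unflagged	low	NA	no
COX3	D	156	RRRSSDDDDD	153	unflagged	high	positive-negative	no
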