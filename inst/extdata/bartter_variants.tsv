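gene_id	hgvs_c	protein	exon_number	exon_length	location_in_exon	bdgp	ess_gained	ese_broken	dmaxent_donor_pct	dmaxent_acceptor_pct
SLC12A1	c.595C>T	p.Arg199Cys	3	76	-34	NA	6	1	NA	NA
SLC12A1	c.728G>A	p.Gly243Glu	5	140	4	3'AS:0.99->0.98	0	0	NA	NA
SLC12A1	c.735C>G	p.Tyr245*	5	140	11	NA	1	5	NA	NA
SLC12A1	c.904C>T	p.Arg302Trp	6	111	40	NA	1	6	NA	NA
SLC12A1	c.905G>A	p.Arg302Gln	6	111	41	NA	2	6	NA	NA
SLC12A1	c.1010C>T	p.Ala337Val	7	112	35	NA	6	2	NA	NA
SLC12A1	c.1304C>T	p.Ala435Val	10	152	4	3'AS:0.87->0.84	2	2	NA	NA
SLC12A1	c.1493C>T	p.Ala498Val	11	108	41	NA	5	2	NA	NA
SLC12A1	c.2221A>T	p.Lys741*	17	141	67	NA	2	4	NA	2438.46
CLCNKB	c.226C>T	p.Arg76*	2	129	-4	5'DS:0.95->0.93	4	1	NA	NA
CLCNKB	c.228A>C	p.Arg76=	2	129	-2	5'DS:0.95->0.84	0	0	-36.73	NA
CLCNKB	c.229G>A	p.Ala77Thr	2	129	-1	NA	0	0	-73.68	NA
CLCNKB	c.229G>C	p.Ala77Pro	2	129	-1	NA	0	0	-55.79	NA
CLCNKB	c.1979C>A	p.Ser660*	18	87	-38	NA	3	5	NA	410.71
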