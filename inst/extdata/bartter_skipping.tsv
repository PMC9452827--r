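gene_id	hgvs_c	variant_type	sites_of_action	splicing_change	consequence	protein_note
SLC12A1	c.728G>A	missense	splice sites	partial skipping of exon 5	p.Gly242Glyfs*2	truncated protein (NKCC2)
SLC12A1	c.735C>G	nonsense	ESEs/ESSs	partial skipping of exon 5	p.Gly242Glyfs*2	truncated protein (NKCC2)
SLC12A1	c.904C>T	missense	ESEs/ESSs	partial skipping of exon 6	in-frame deletion (codon 289-325)	37 aa loss in TMH4 and cytoplasmic domain (NKCC2)
SLC12A1	c.905G>A	missense	ESEs/ESSs	partial skipping of exon 6	in-frame deletion (codon 289-325)	37 aa loss in TMH4 and cytoplasmic domain (NKCC2)
SLC12A1	c.1304C>T	missense	splice sites	complete skipping of exon 10	p.Gly434Glyfs*58	truncated protein (NKCC2)
SLC12A1	c.1493C>T	missense	ESEs/ESSs	partial skipping of exon 11	in-frame deletion (codon 485-520)	36 aa loss in TMH8 and cytoplasmic domain (NKCC2)
SLC12A1	c.2221A>T	nonsense	ESEs/ESSs	complete skipping of exon 17	in-frame deletion (codon 719-765)	47 aa loss between TMH11 and TMH12 (NKCC2)
CLCNKB	c.226C>T	nonsense	splice sites	partial skipping of exon 2	in-frame deletion (codon 34-77)	43 aa loss in TMH1 (ClC-Kb)
CLCNKB	c.228A>C	synonymous	splice sites	partial skipping of exon 2	in-frame deletion (codon 34-77)	43 aa loss in TMH1 (ClC-Kb)
CLCNKB	c.229G>A	missense	splice sites	partial skipping of exon 2	in-frame deletion (codon 34-77)	43 aa loss in TMH1 (ClC-Kb)
CLCNKB	c.229G>C	missense	splice sites	partial skipping of exon 2	in-frame deletion (codon 34-77)	43 aa loss in TMH1 (ClC-Kb)
CLCNKB	c.1979C>A	nonsense	ESEs/ESSs	complete skipping of exon 18	in-frame deletion (codon 644-672)	29 aa loss in cytoplasmic domain (ClC-Kb)
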