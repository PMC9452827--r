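construct_id	variant	cell_line	exclusion_percent	pattern
CLCNKB_Ex2	WT	HEK293T	67.9	both
CLCNKB_Ex2	c.226C>T	HEK293T	87.8	both
CLCNKB_Ex2	c.228A>C	HEK293T	91.0	both
CLCNKB_Ex2	c.229G>A	HEK293T	88.1	both
CLCNKB_Ex2	c.229G>C	HEK293T	74.4	both
CLCNKB_Ex2	WT	Hela	51.1	both
CLCNKB_Ex2	c.226C>T	Hela	85.7	both
CLCNKB_Ex2	c.228A>C	Hela	85.6	both
CLCNKB_Ex2	c.229G>A	Hela	83.1	both
CLCNKB_Ex2	c.229G>C	Hela	78.4	both
CLCNKB_Ex18	WT	HEK293T	72.3	both
CLCNKB_Ex18	WT	Hela	70.7	both
CLCNKB_Ex18	c.1979C>A	HEK293T	100	backbone_only
CLCNKB_Ex18	c.1979C>A	Hela	100	backbone_only
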