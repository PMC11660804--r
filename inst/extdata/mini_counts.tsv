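gene_id	s1	s2
gA	5	0
gB	12	7
gC	3	9
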