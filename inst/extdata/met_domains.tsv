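# Met protein domain table (short-isoform residue numbering, as used in
# clinical reports where T992I sits in the juxtamembrane domain and H1094Y
# in the tyrosine kinase domain). Override with your own table as needed.
domain_name	start_residue	end_residue
Sema	27	515
PSI	519	562
TIG	563	932
JM	956	1009
TK	1078	1345
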