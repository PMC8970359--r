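# SYNTHETIC presence/absence matrix of family-qualified Cdv domain characters
# per archaeal lineage, constructed from the published per-group domain
# distribution statements.
taxon	CdvB:Snf7	CdvB:MIM2	CdvB:BWH	CdvB:ANCHR	CdvB:MIM1	CdvA:CdvA_alpha	CdvA:CdvA_beta	CdvA:BWI	CdvA:MIM2	CdvC:MIT	CdvC:AAA_ATPase	CdvC:Vps4_C
Euryarchaeota	1	0	0	0	0	0	0	0	0	1	1	1
Asgard	1	1	0	1	1	0	0	0	0	1	1	1
Thaumarchaeota	1	1	0	0	0	1	1	0	1	1	1	1
Crenarchaeota	1	1	1	0	0	1	1	1	0	1	1	1
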