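taxon_id	genus	group	lineage
tax_Bacteria	Genus_Bacteria	Bacteria	cellular;Bacteria
tax_CPR	Genus_CPR	CPR	cellular;CPR
tax_Archaea	Genus_Archaea	Archaea	cellular;Archaea
self	Genus_self	Bacteria	cellular;self
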