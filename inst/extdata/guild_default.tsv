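genus	guild
Sideroxydans	FeOB
Pedomicrobium	FeOB
Leptothrix	FeOB
Gallionella	FeOB
Geobacter	FeRB
Geothrix	FeRB
Clostridium	FeRB
Rhodoferax	FeRB
Pseudomonas	FeRB
Desulfovibrio	FeRB
Shewanella	FeRB
Anaeromyxobacter	FeRB
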