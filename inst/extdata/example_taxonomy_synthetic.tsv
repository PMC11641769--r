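id	domain_of_life	phylum	class
SourceBac_01	Bacteria	SourcePhylum	
SourceBac_02	Bacteria	SourcePhylum	
SourceBac_03	Bacteria	SourcePhylum	
SourceBac_04	Bacteria	SourcePhylum	
SourceBac_05	Bacteria	SourcePhylum	
Organelle_01	Eukaryota	Streptophyta	
Organelle_02	Eukaryota	Streptophyta	
Organelle_03	Eukaryota	Streptophyta	
Organelle_04	Eukaryota	Streptophyta	
Organelle_05	Eukaryota	Streptophyta	
OtherBac_01	Bacteria	OtherPhylum	
OtherBac_02	Bacteria	OtherPhylum	
OtherBac_03	Bacteria	OtherPhylum	
OtherBac_04	Bacteria	OtherPhylum	
OtherBac_05	Bacteria	OtherPhylum	
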