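isomir	transcript_id	window_start	seed_type	region
hsa-miR-192-5p|0	ENST00000361390	132	8mer	3UTR
hsa-miR-192-5p|0	ENST00000361390	418	other	CDS
hsa-miR-192-5p|+1	ENST00000361453	87	6mer	5UTR
hsa-miR-10a-5p|0	ENST00000361624	233	7mer-m8	3UTR
hsa-miR-10a-5p|0	ENST00000361739	51	other	CDS
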