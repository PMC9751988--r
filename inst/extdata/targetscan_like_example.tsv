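isomir	transcript_id	site_start	seed_type
hsa-miR-192-5p|0	ENST00000361390	133	8mer
hsa-miR-192-5p|0	ENST00000361624	77	6mer
hsa-miR-192-5p|+1	ENST00000361453	210	7mer-A1
hsa-miR-10a-5p|0	ENST00000361624	234	7mer-m8
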