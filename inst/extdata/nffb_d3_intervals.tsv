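name	chrom	start	end	source
qNFFB-D3-1	D3	17130008	41839226	QTL
bsa_region_1	D3	41779195	41836120	BSA
bsa_region_2	D3	41836768	41872287	BSA
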