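label	mass_da
Carbamidomethylation	57.02146
Oxidation	15.99491
Deamidation	0.98402
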