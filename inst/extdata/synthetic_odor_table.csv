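compound_id,group,peak_area,odor_threshold,descriptors
VC001,G1,120000,0.05,sweet;fruity
VC001,G2,150000,0.05,sweet;fruity
VC002,G1,80000,0.8,green;herbal
VC002,G2,40000,0.8,green;herbal
VC003,G1,5000,2.5,woody
VC003,G2,9000,2.5,woody
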