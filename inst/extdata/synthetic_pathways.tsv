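pathway_id	feature_id
path01	F0001
path01	F0002
path01	F0003
path02	F0002
path02	F0004
path02	F0005
path02	F0006
path03	F0007
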