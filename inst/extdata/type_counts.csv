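type,n
all,682
POAG,208
PACG,35
secondary,53
unclassified,386
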