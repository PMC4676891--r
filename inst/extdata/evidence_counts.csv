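category,basis,participants,eyes
1,vcdr,155,197
1,vcdr_asymmetry,113,113
2,vcdr,330,511
2,vcdr_asymmetry,43,43
2b,all,5,10
3,all,36,76
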