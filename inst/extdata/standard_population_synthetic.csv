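age_band,population
40-49,8742800
50-59,6405400
60-69,4964700
70-79,2988600
80+,1233800
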