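factor,level,total,glaucoma
total,all,13591,682
age,40-49,4889,93
age,50-59,3577,130
age,60-69,2773,178
age,70-79,1653,178
age,80+,699,103
sex,female,7345,328
sex,male,6246,354
ethnicity,Hausa,3375,130
ethnicity,Yoruba,2669,156
ethnicity,Igbo,1918,149
ethnicity,Fulani,840,30
ethnicity,Kanuri,353,18
ethnicity,Tiv,342,11
ethnicity,Ijaw,251,15
ethnicity,Urhobo,245,7
ethnicity,Ibibio,212,12
ethnicity,Nupe,211,11
ethnicity,Others,3117,139
literacy,literate,5925,248
literacy,illiterate,7666,434
residence,rural,10540,520
residence,urban,3051,162
visual_status,not_blind,13022,546
visual_status,blind,569,136
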