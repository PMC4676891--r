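name,value
enumerated,15027
examined,13591
clusters,305
glaucoma_persons,682
glaucoma_eyes,950
aware_persons,38
blind_glaucoma_persons,136
blind_persons,569
glaucoma_eyes_va_worse_3_60,365
secondary_persons,53
gonioscoped_primary,243
poag_gonioscoped,208
pacg_gonioscoped,35
level1_persons,268
level2_persons,373
level2b_persons,5
level3_persons,36
dx_photo_vcdr_eyes,352
dx_clinical_vcdr_eyes,294
dx_disc_not_seen_eyes,36
vcdr_trigger_persons,770
vcdr_trigger_diagnosed,485
asym_trigger_persons,3768
asym_trigger_diagnosed,156
vf_needed_eyes,4995
vf_needed_persons,4538
vf_available_eyes,3016
vf_available_persons,2725
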