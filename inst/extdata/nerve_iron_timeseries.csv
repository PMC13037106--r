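subject_id,compartment,time_days,iron_mass,iron_mass_units,uncertainty
nerve_mean,tissue,1,3.57,ug,0.33
nerve_mean,tissue,3,2.13,ug,0.22
nerve_mean,tissue,7,1.40,ug,0.52
nerve_mean,tissue,14,0.34,ug,0.09
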