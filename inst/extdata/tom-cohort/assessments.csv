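"assessment_id","assessment_date","body_mass","height","body_mass_index","waist_circumference","hip_circumference","waist_to_hip_ratio","waist_to_height_ratio","body_fat_mass","age_at_assessment"
"tomcond1","2014-11-20",,,24.3,,,,,,
"tomcond2","2015-11-20",,,24.3,,,,,,
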