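"person_id","gender","date_of_birth"
"tom","Male","2000-10-15"
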