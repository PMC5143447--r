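"person_id","assessment_id"
"tom","tomcond1"
"tom","tomcond2"
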