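n_persons: 50
seed: 42
n_assessments: 2
age_range: [10, 19]
gender_ratio: 0.5
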