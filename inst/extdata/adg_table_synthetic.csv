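class_lower_kg,adg_kg_per_day
250,0.8
300,0.9
350,1.0
400,0.9
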