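template_id	primer	covered	start	total	internal	terminal3_hit	mismatch_positions	risk	rationale
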