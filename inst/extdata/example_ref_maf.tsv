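variant_id	maf
1:1000:A:G	0.31
1:2000:C:T	0.12
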