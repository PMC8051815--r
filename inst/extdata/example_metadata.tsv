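sample_id	center	kit	sex	phenotype	apoe_cov
S001	C1	KitA	F	case	0
S002	C2	KitB	M	control	1
S003	C3	KitB	F	control	2
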