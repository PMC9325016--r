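id	formula	lb	ub
v1	--> acetate	0	10
v2	acetate --> ACCOA	0	100
v3	acetate --> CIT	0	100
v4	CIT -->	0	100
v5	ACCOA --> OAA	0	100
v6	OAA <=> PEP + CO2	0	100
v7	PEP <=> T3P	0	100
v8	PEP --> PYR	0	100
v9	PYR --> PROT	0	100
v10	PROT -->	0	100
v11	T3P <=> F6P	0	100
v12	F6P <=> G6P	0	100
v13	G6P --> CARB	0	100
v14	CARB -->	0	100
v15	E4P + X5P --> F6P + T3P	0	100
v16	--> E4P	0	0.3
v17	--> X5P	0	0.3
v18	CO2 -->	0	100
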