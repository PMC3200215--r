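sample	age	gender	diagnosis	group
Control 1	23	M	Pseudotumor cerebri	control
Control 2	28	M	Headaches	control
Control 3	32	F	Pseudotumor cerebri	control
Control 4	39	F	Pseudotumor cerebri	control
Control 5	44	F	Pseudotumor cerebri	control
A-T 1	21	F	A-T patient	case
A-T 2	21	F	A-T patient	case
A-T 3	26	F	A-T patient	case
A-T 4	20	M	A-T patient	case
A-T 5	22	M	A-T patient	case
A-T 6	23	F	A-T patient	case
A-T 7	20	F	A-T patient	case
A-T 8	22	F	A-T patient	case
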