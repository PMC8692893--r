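region	start	end
FR1	1	20
CDR1	21	28
FR2	29	38
HV2	39	46
FR3a	47	56
FR3b	57	68
CDR3	69	80
FR4	81	90
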