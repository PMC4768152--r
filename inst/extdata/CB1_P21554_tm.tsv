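protein_id	tm_index	start	end	topology
CB1_P21554_synthetic	1	117	142	extracellular
CB1_P21554_synthetic	2	155	175	extracellular
CB1_P21554_synthetic	3	188	212	extracellular
CB1_P21554_synthetic	4	233	255	extracellular
CB1_P21554_synthetic	5	274	299	extracellular
CB1_P21554_synthetic	6	345	365	extracellular
CB1_P21554_synthetic	7	378	399	extracellular
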