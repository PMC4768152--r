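protein_id	tm_index	start	end	topology
TSPO_TM5_synthetic	1	6	29	extracellular
TSPO_TM5_synthetic	2	40	63	extracellular
TSPO_TM5_synthetic	3	74	97	extracellular
TSPO_TM5_synthetic	4	105	128	extracellular
TSPO_TM5_synthetic	5	137	159	extracellular
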