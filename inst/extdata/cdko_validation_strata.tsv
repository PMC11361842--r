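pathway_a	pathway_b	predicted_sl	predicted_non_sl	validated_sl	validated_non_sl
Apoptosis	Apoptosis	350	300	295	355
Apoptosis	Autosis	20	20	7	33
Apoptosis	Mitotic	80	80	84	76
Mitotic	Mitotic	50	50	67	33
Autosis	Mitotic	16	20	9	27
Autosis	Autosis	1	0	0	1
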