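screen	validated_sl	validated_non_sl
22Rv1_round1_random_pairs	88	1137
22Rv1_round2_model_selected	462	525
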