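pattern	n_hits	n_recognized	tf	n_regulated
co_expression	155	124	TEC1p	109
co_expression	155	124	STE12p	91
co_expression	155	124	TEC1p+STE12p	76
contrast	15	5	TEC1p	3
contrast	15	5	STE12p	5
contrast	15	5	TEC1p+STE12p	3
one_interval_shift	44	27	TEC1p	25
one_interval_shift	44	27	STE12p	22
one_interval_shift	44	27	TEC1p+STE12p	20
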