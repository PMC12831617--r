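characteristic	case_pos	case_neg	ctrl_pos	ctrl_neg	reported_p
HBsAg_positive	0	40	3	46	0.2492
male	31	9	33	16	0.3474
MELD_below_10	8	32	6	43	0.3863
HCV_Ab_positive	40	0	49	0	1
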