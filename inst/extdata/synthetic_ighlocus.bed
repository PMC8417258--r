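IGH_minilocus	1500	1795	IGHV1-1|V	0	+
IGH_minilocus	3295	3590	IGHV1-2|V	0	+
IGH_minilocus	5090	5385	IGHV2-1|V	0	+
IGH_minilocus	6885	7180	IGHV2-2|V	0	+
IGH_minilocus	8680	8975	IGHV3-1|V	0	+
IGH_minilocus	10475	10770	IGHV3-2|V	0	+
IGH_minilocus	12270	12565	IGHV4-1|V	0	+
IGH_minilocus	14065	14360	IGHV4-2|V	0	+
IGH_minilocus	15860	15875	IGHD1-15|D	0	+
IGH_minilocus	17375	17385	IGHD2-10|D	0	+
IGH_minilocus	18885	18913	IGHD3-28|D	0	+
IGH_minilocus	20413	20463	IGHJ1|J	2	+
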