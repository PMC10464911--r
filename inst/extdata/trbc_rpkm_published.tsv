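species	dataset	tissue	input_reads	rpkm_trbc1	rpkm_trbc2	ratio_printed	flagged
Oncorhynchus tshawytscha	SRR6273681	spleen	110639563	45.7	6.7	6.8	FALSE
Oncorhynchus tshawytscha	SRR3986817	spleen	14921851	72.5	10.0	7.3	FALSE
Oncorhynchus tshawytscha	SRR3986815	spleen	16726316	68.0	11.3	6.0	FALSE
Oncorhynchus kisutch	SRR5333378	spleen	70389516	171.8	70.8	2.4	FALSE
Oncorhynchus kisutch	SRR5333374	spleen	76816418	208.6	62.4	3.3	FALSE
Oncorhynchus kisutch	SRR5333360	spleen	66842954	150.4	48.2	2.6	TRUE
Oncorhynchus mykiss	SRR11972660	spleen	1494649	47.9	20.5	2.3	FALSE
Oncorhynchus mykiss	SRR11972662	spleen	687545	79.9	24.4	3.3	FALSE
Oncorhynchus mykiss	SRR11972726	spleen	1036767	115.4	41.0	2.8	FALSE
Oncorhynchus gorbuscha	SRR9841114	spleen	83100156	150.4	48.2	3.1	TRUE
Salmo trutta	SRR6666113	multi_tissue	46960387	132.4	14.3	9.3	FALSE
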