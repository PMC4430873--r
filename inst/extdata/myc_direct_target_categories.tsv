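category	n_genes
RNA Pol I activity	7
snoRNP function	15
40S subunit assembly, processing, maturation	18
60S subunit assembly, processing, maturation	17
processing of both subunits	3
40S ribosomal subunit	19
60S ribosomal subunit	21
Mitochondrial ribosome	2
Translation factors	6
tRNA processing, maturation	6
Metabolism	5
Transcription, RNA processing	5
Mitochondrial function	4
Other, unknown	11
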