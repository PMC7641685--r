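hypothesis	statistic	x	y	alternative	published_bound
H01	var_ratio	CS	OS	less	0.1
H02	var_ratio	DA	DACS	greater	2.3
H03	var_ratio	OS	DACS	greater	2.2
H04	mean_diff	CS	OS	greater	8.56
H05	mean_diff	DACS	DA	greater	13.25
H06	mean_diff	DACS	CS	greater	1.45
H07	mean_diff	DA	OS	greater	-4.56
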