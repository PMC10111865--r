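arm,gain_freq,loss_freq
chr1p,0.151,0.055
chr1q,0.31,0.07
chr2p,0.086,0.269
chr2q,0.357,0.163
chr3p,0.147,0.011
chr3q,0.137,0.034
chr4p,0.001,0.106
chr4q,0.081,0.036
chr5p,0.36,0.08
chr5q,0.229,0.228
chr6p,0.029,0.27
chr6q,0.18,0.019
chr7p,0.06,0.338
chr7q,0.121,0.082
chr8p,0.33,0.163
chr8q,0.28,0.281
chr9p,0.104,0.001
chr9q,0.171,0.277
chr10p,0.039,0.066
chr10q,0.042,0.193
chr11p,0.315,0.054
chr11q,0.019,0.035
chr12p,0.064,0.013
chr12q,0.264,0.498
chr13q,0.071,0.18
chr14q,0.155,0.22
chr15q,0.276,0.333
chr16p,0.247,0.079
chr16q,0.079,0.24
chr17p,0.214,0.023
chr17q,0.123,0.212
chr18p,0.318,0.139
chr18q,0.009,0.066
chr19p,0.074,0.135
chr19q,0.227,0.204
chr20p,0.224,0.009
chr20q,0.3,0.014
chr21q,0.483,0.011
chr22q,0.108,0.152
chrXp,0.311,0.08
chrXq,0.149,0.284
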