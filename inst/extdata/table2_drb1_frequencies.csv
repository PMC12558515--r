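# HLA-DRB1 allele frequencies in four US ethnic groups (AFND-style,
# 2n-alleles basis, decimal), transcribed verbatim from the published
# ethnicity-stratified hotspot table. Blank cells are preserved as blank
# ("not typed"), distinct from a reported frequency of 0.
allele,Caucasian,African_American,Hispanic,Asian,n_Caucasian,n_African_American,n_Hispanic,n_Asian
DRB1*01:02,0.0202,0.0399,0.033,0.0003,1070,2411,1999,1772
DRB1*01:03,0.0192,0.0023,0.0063,0.0003,1070,2411,1999,1772
DRB1*03:01,0.1039,0.0707,0.0733,0.0537,1070,2411,1999,1772
DRB1*03:05,0.001,0.0002,0.0003,0,1070,2411,1999,1772
DRB1*03:06,,0.0002,0,0,1070,2411,1999,1772
DRB1*04:01,0.1039,0.0229,0.0145,0.0091,1070,2411,1999,1772
DRB1*04:02,0.0039,0.0004,0.0195,0.0037,1070,2411,1999,1772
DRB1*04:07,0.0154,0.004,0.0643,0.0014,1070,2411,1999,1772
DRB1*04:08,0.0058,0.0006,0.0035,0.0014,1070,2411,1999,1772
DRB1*04:14,,0,0.0003,0,1070,2411,1999,1772
DRB1*04:17,,0,0.0005,0,1070,2411,1999,1772
DRB1*04:18,,0,0.0003,0,1070,2411,1999,1772
DRB1*07:01,0.126,0.0977,0.1046,0.082,1070,2411,1999,1772
DRB1*07:03,,0,0,0.0003,1070,2411,1999,1772
DRB1*08:02,0.0029,0.001,0.0733,0.013,1070,2411,1999,1772
DRB1*08:09,,0,0,0.0023,1070,2411,1999,1772
DRB1*09:01,0.0106,0.0316,0.0095,0.1018,1070,2411,1999,1772
DRB1*10:01,0.0077,0.0185,0.0145,0.0311,1070,2411,1999,1772
DRB1*12:01,0.0173,0.0395,0.012,0.0289,1070,2411,1999,1772
DRB1*12:02,,0.0027,0.0008,0.0741,1070,2411,1999,1772
DRB1*12:08,,0,0,0.0003,1070,2411,1999,1772
DRB1*13:02,0.0519,0.0645,0.0388,0.0362,1070,2411,1999,1772
DRB1*13:16,,0.0004,0,0,1070,2411,1999,1772
DRB1*13:31,,0.0006,0,0,1070,2411,1999,1772
DRB1*13:36,,0.0002,0,0,1070,2411,1999,1772
DRB1*15:01,0.1394,0.0293,0.0668,0.0792,1070,2411,1999,1772
DRB1*15:02,0.0077,0.0017,0.0133,0.0809,1070,2411,1999,1772
DRB1*15:03,0.001,0.1175,0.0113,0.0006,1070,2411,1999,1772
DRB1*15:04,,0,0.0003,0.0006,1070,2411,1999,1772
DRB1*15:06,,0,0,0.004,1070,2411,1999,1772
DRB1*15:07,,0,0,0.0003,1070,2411,1999,1772
DRB1*15:10,0.001,,,,1070,2411,1999,1772
DRB1*15:11,0.001,,,,1070,2411,1999,1772
DRB1*15:14,,0,0,0.0003,1070,2411,1999,1772
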