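chrom,size_bp,n_snps,first_pos,last_pos,reported_span_bp,reported_coverage_pct,reported_bp_per_snp,reported_max_gap_bp,gap_before,gap_after
Pp01,47851208,10762,60526,47767955,47707429,99.7,4433.0,820485,20222054,21042539
Pp02,30405870,5464,202123,30328437,30126314,99.1,5513.6,1124185,12233140,13357325
Pp03,27368013,5014,80888,27263572,27182684,99.3,5421.4,839584,11883898,12723482
Pp04,25843236,5153,66757,25842651,25775894,99.7,5002.1,1264812,18802344,20067156
Pp05,18496696,4385,140775,18446896,18306121,99.0,4174.7,951113,6809932,7761045
Pp06,30767194,5963,76624,30724506,30647882,99.6,5139.7,455992,21314594,21770586
Pp07,22388614,4519,1825,22319659,22317834,99.7,4938.7,918858,4329583,5248441
Pp08,22573980,4122,81834,22513105,22431271,99.4,5441.8,956262,7430911,8387173
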