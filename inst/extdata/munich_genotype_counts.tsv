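# Genotype counts of the MtnA 3' UTR indel polymorphism, wild-caught
# D. melanogaster, Munich seasonal survey (collections 2016-2017).
# Columns: stratum = collection; counts are individuals per genotype.
stratum	sex	n_deldel	n_delnon	n_nonnon
June 2016	All	160	31	3
Sept 2016	All	120	22	1
June 2017	All	131	25	3
Sept 2017	All	99	18	1
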