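# Deletion-allele chromosome counts per collection and sex, Munich
# seasonal survey. n_chromosomes = 2 x flies genotyped in that stratum;
# n_deletion = deletion-bearing chromosomes (frequency x chromosomes).
stratum	sex	n_chromosomes	n_deletion
June 2016	F	224	203
June 2016	M	164	148
Sept 2016	F	192	178
Sept 2016	M	94	84
June 2017	F	144	130
June 2017	M	174	157
Sept 2017	F	176	160
Sept 2017	M	60	56
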